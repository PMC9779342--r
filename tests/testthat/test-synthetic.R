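test_that("generation is byte-identical for identical (model, seed)", {
  mod <- synthetic_model_shares(c(0.1, 0.05), n = 100, m = 3)
  a <- generate_cohort(mod, seed = 7)
  b <- generate_cohort(mod, seed = 7)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, generate_cohort(mod, seed = 8)$data))
})

test_that("a null model yields an outcome uncorrelated with every predictor", {
  n <- 10000
  mod <- synthetic_model_shares(c(0, 0, 0), n = n, m = 3)
  co <- generate_cohort(mod, seed = 42)
  preds <- setdiff(names(co$data), "y")
  cors <- vapply(preds, function(v) cor(co$data[[v]], co$data$y), numeric(1))
  expect_true(all(abs(cors) < 4 / sqrt(n)))
})

test_that("template cohort marginals match the declared parameters", {
  mod <- salia_template(n = 547)
  co <- generate_cohort(mod, seed = 3)
  d <- co$data
  n <- nrow(d)
  # continuous: mean within 3 standard errors of the declared marginal
  expect_lt(abs(mean(d$bmi_fu2) - 27.29), 3 * 4.34 / sqrt(n))
  expect_lt(abs(mean(d$no2) - 37.21), 3 * 11.16 / sqrt(n))
  expect_lt(abs(sd(d$no2) / 11.16 - 1), 0.15)
  # rare binary: prevalence within 3 binomial standard errors
  p <- 0.024
  expect_lt(abs(mean(d$current_smoking) - p), 3 * sqrt(p * (1 - p) / n))
  # SNP coding and allele-frequency sanity
  expect_true(all(d$snp01 %in% 0:2))
  # correlated pollutants: NO2 and NOx share the latent block correlation
  expect_gt(cor(d$no2, d$nox), 0.45)
  # outcome is a z-score
  expect_equal(mean(d$y), 0, tolerance = 1e-12)
  expect_equal(sd(d$y), 1, tolerance = 1e-12)
})

test_that("continuous blocks realize their latent correlation", {
  mod <- synthetic_model(1e4, categories = list(
    b = list(rho = 0.9, members = lapply(1:5, function(j)
      list(name = paste0("x", j))))))
  co <- generate_cohort(mod, seed = 5)
  C <- cor(co$data[paste0("x", 1:5)])
  off <- C[upper.tri(C)]
  expect_true(all(off > 0.85 & off < 0.95))
})

test_that("analytic contributions are exact in tractable cases", {
  # all effects zero -> all shares zero, R^2 = 0
  tc0 <- true_contributions(synthetic_model_shares(c(0, 0), n = 100))
  expect_equal(unname(tc0$shares), rep(0, 4))
  expect_equal(tc0$r2, 0)

  # two independent single-column units with equal effects and noise chosen
  # for R^2 = 0.5: shares 0.25 each by symmetry
  tc <- true_contributions(
    synthetic_model_shares(c(0.25, 0.25), n = 100, m = 1, rho = 0,
                           n_singles = 0))
  expect_equal(unname(tc$shares), c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(tc$r2, 0.5, tolerance = 1e-12)

  # one informative category carries the whole R^2
  tc1 <- true_contributions(
    synthetic_model_shares(c(0.3), n = 100, m = 4, n_singles = 2))
  expect_equal(unname(tc1$shares[["cat1"]]), 0.3, tolerance = 1e-12)
  expect_equal(tc1$r2, 0.3, tolerance = 1e-12)
})

test_that("analytic contributions agree with a large-sample empirical check", {
  # mixed types and nonzero rho: Monte Carlo LMG on the raw members should
  # approach the covariance-algebra result
  mod <- synthetic_model(
    4e4,
    singles = list(list(name = "s1", effect = 0.2)),
    categories = list(
      a = list(rho = 0.6, members = list(
        list(name = "a1", effect = 0.3),
        list(name = "a2", type = "binary", prevalence = 0.3, effect = 0.4))),
      b = list(rho = 0.4, members = list(
        list(name = "b1", type = "snp", maf = 0.3, effect = 0.25),
        list(name = "b2", effect = -0.2)))),
    noise_sd = 1)
  tc <- true_contributions(mod)
  co <- generate_cohort(mod, seed = 9)
  X <- as.matrix(co$data[, c("s1", "a1", "a2", "b1", "b2")])
  emp <- lmg(X, co$data$y, list(s1 = "s1", a = c("a1", "a2"),
                                b = c("b1", "b2")))
  expect_lt(max(abs(unname(emp) - unname(tc$shares))), 0.01)
})

test_that("contributions are equivariant under category relabeling", {
  build <- function(shares) synthetic_model_shares(shares, n = 100, m = 2)
  t1 <- true_contributions(build(c(0.2, 0.05)))
  t2 <- true_contributions(build(c(0.05, 0.2)))
  expect_equal(unname(t1$shares[["cat1"]]), unname(t2$shares[["cat2"]]),
               tolerance = 1e-12)
  expect_equal(unname(t1$shares[["cat2"]]), unname(t2$shares[["cat1"]]),
               tolerance = 1e-12)
})

test_that("model invariants are enforced", {
  expect_error(synthetic_model(10, categories = list(
    b = list(rho = 1, members = list(list(name = "x"))))), "rho")
  expect_error(synthetic_model(10, singles = list(
    list(name = "b", type = "binary"))), "prevalence")
  expect_error(synthetic_model(
    10, singles = list(list(name = "a"), list(name = "b")),
    single_cor = matrix(c(1, 2, 2, 1), 2)), "positive definite")
})
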