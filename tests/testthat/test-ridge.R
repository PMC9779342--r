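test_that("lambda = 0 with a full-rank design reproduces OLS", {
  pr <- random_ridge_problem(n = 40, p = 6, n_unpen = 2, seed = 1)
  fit <- fit_ridge(pr, 0)
  ols <- lm.fit(cbind(1, pr$X), pr$y)$coefficients
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-10)
})

test_that("single penalized predictor matches the closed form", {
  set.seed(2)
  n <- 25
  x <- as.numeric(scale(rnorm(n), scale = FALSE))  # centered
  y <- 0.8 * x + rnorm(n)
  pr <- ridge_problem(y, matrix(x), penalty = 1)
  for (lam in c(0.01, 0.1, 1)) {
    expect_equal(unname(fit_ridge(pr, lam)$coefficients),
                 sum(x * y) / (sum(x^2) + 2 * n * lam), tolerance = 1e-12)
  }
})

test_that("the closed form agrees with a generic numerical minimizer", {
  for (seed in 1:5) {
    pr <- random_ridge_problem(n = 20, p = 10, n_unpen = 3, seed = seed)
    lam <- exp(runif(1, log(0.01), log(1)))
    fit <- fit_ridge(pr, lam)
    ora <- optim_ridge(pr$X, pr$y, pr$penalty, lam)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) -
                        c(ora$intercept, ora$coefficients))), 1e-8)
  }
})

test_that("huge lambda zeroes the penalized block, leaving OLS on singles", {
  pr <- random_ridge_problem(n = 50, p = 8, n_unpen = 3, seed = 3)
  fit <- fit_ridge(pr, 1e8)
  expect_true(all(abs(fit$coefficients[pr$penalty == 1]) < 1e-6))
  Xu <- pr$X[, pr$penalty == 0, drop = FALSE]
  ols <- lm.fit(cbind(1, Xu), pr$y)$coefficients
  expect_equal(unname(fit$coefficients[pr$penalty == 0]), unname(ols[-1]),
               tolerance = 1e-6)
})

test_that("penalized coefficient norm shrinks monotonically in lambda", {
  pr <- random_ridge_problem(n = 40, p = 9, n_unpen = 2, seed = 4)
  lams <- c(0, 0.01, 0.1, 1, 10)
  norms <- vapply(lams, function(l)
    sqrt(sum(fit_ridge(pr, l)$coefficients[pr$penalty == 1]^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("the lambda grid is log-spaced, decreasing, and degenerate-safe", {
  pr <- random_ridge_problem(seed = 5)
  g <- lambda_grid(pr, n_lambda = 3, min_ratio = 0.01)
  expect_equal(g[2] / g[1], 0.1, tolerance = 1e-12)
  expect_equal(g[3] / g[2], 0.1, tolerance = 1e-12)

  g100 <- lambda_grid(pr)
  expect_length(g100, 100)
  expect_true(all(diff(g100) < 0))

  # response orthogonal to every penalized predictor: anchor near zero but
  # the grid stays positive and valid
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40)
  y <- y - X %*% solve(crossprod(X), crossprod(X, y))  # exact orthogonality
  pr2 <- ridge_problem(drop(y), X, rep(1, 3))
  g2 <- lambda_grid(pr2)
  expect_true(all(g2 > 0))
  expect_true(all(diff(g2) < 0))
})

test_that("cross-validation is deterministic and shrinkage-sensible", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5)
  noise <- ridge_problem(rnorm(n), X, rep(1, 5))
  g <- lambda_grid(noise, 50)
  l1 <- cv_select_lambda(noise, 5, g, seed = 11)
  expect_identical(l1, cv_select_lambda(noise, 5, g, seed = 11))

  # pure-noise response: lambda lands in the larger half in most runs
  picks <- vapply(1:10, function(s) {
    pr <- ridge_problem(rnorm(n), X, rep(1, 5))
    cv_select_lambda(pr, 5, g, seed = s)
  }, numeric(1))
  expect_gt(mean(picks >= g[25]), 0.5)

  # strong noiseless signal: lambda in the smallest decile
  sig <- ridge_problem(drop(X %*% c(1, -1, 0.5, 2, -0.7)), X, rep(1, 5))
  gs <- lambda_grid(sig, 50)
  ls <- cv_select_lambda(sig, 5, gs, seed = 12)
  expect_lte(ls, gs[46])
})

test_that("weight normalization follows the signed-sum formula", {
  expect_equal(as.numeric(normalize_weights(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(attr(normalize_weights(c(0, 0, 0)), "fallback"), "all_zero")
  expect_equal(unname(normalize_weights(c(2, 1, 1))), c(0.5, 0.25, 0.25))
  # mixed signs: sum is one but weights can leave [-1, 1]
  w <- normalize_weights(c(3, -1))
  expect_equal(unname(w), c(1.5, -0.5))
  expect_equal(sum(w), 1)
})

test_that("weights are scale invariant and sum to one in every branch", {
  set.seed(8)
  for (i in 1:20) {
    g <- rnorm(sample(2:6, 1))
    w <- normalize_weights(g)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    expect_equal(as.numeric(w), as.numeric(normalize_weights(3.7 * g)),
                 tolerance = 1e-12)
  }
})

test_that("near-cancellation triggers the uniform guard", {
  w <- normalize_weights(c(1, -1 + 1e-12))
  expect_equal(attr(w, "fallback"), "cancellation")
  expect_equal(as.numeric(w), c(0.5, 0.5))
})

test_that("learned weights recover a noiseless single-category signal", {
  set.seed(9)
  n <- 200
  tab <- data.frame(a1 = rnorm(n), a2 = rnorm(n), b1 = rnorm(n),
                    s = rnorm(n))
  tab$y <- 2 * tab$a1 + 1 * tab$a2          # only category A matters
  d <- study_design("y", singles = "s",
                    categories = list(A = c("a1", "a2"), B = "b1"))
  st <- standardization_stats(tab, d)
  tr <- standardize(tab, d, st)
  cfg <- analysis_config(B = 1, cv_repeats = 3, seed = 1)
  lw <- learn_category_weights(tr, d, cfg, seed = 21)
  wA <- lw$weights$A
  # standardized coefficients proportional to (2*sd(a1), 1*sd(a2))
  expected <- c(2 * sd(tab$a1), sd(tab$a2))
  expect_equal(unname(wA), unname(expected / sum(expected)),
               tolerance = 0.02)
  expect_equal(sum(lw$weights$B), 1)
})

test_that("cv_repeats = 1 equals one CV + fit run", {
  tab <- toy_table(80, seed = 10)
  d <- toy_design()
  st <- standardization_stats(tab, d)
  tr <- standardize(tab, d, st)
  cfg <- analysis_config(B = 1, cv_repeats = 1, cv_folds = 5, n_lambda = 30,
                         seed = 1)
  lw <- learn_category_weights(tr, d, cfg, seed = 5)

  X <- as.matrix(tr[, c(d$singles, c("no2", "nox", "pm", "current", "pack"))])
  pr <- ridge_problem(tr$y, X, c(0, 0, 0, 1, 1, 1, 1, 1))
  g <- lambda_grid(pr, 30)
  lam <- cv_select_lambda(pr, 5, g, seed = derive_seed_ref(5, 303L, 1L))
  fit <- fit_ridge(pr, lam)
  expect_equal(unname(lw$gamma), unname(fit$coefficients), tolerance = 1e-12)
})

test_that("constant training columns are dropped, zeroed and flagged", {
  tab <- toy_table(50, seed = 11)
  tab$current <- 0  # degenerate binary member
  d <- toy_design()
  st <- standardization_stats(tab, d)
  tr <- standardize(tab, d, st)
  cfg <- analysis_config(B = 1, cv_repeats = 2, n_lambda = 20, seed = 1)
  lw <- learn_category_weights(tr, d, cfg, seed = 3)
  expect_true(any(grepl("degenerate_column:current", lw$flags)))
  expect_equal(unname(lw$gamma[["current"]]), 0)
  expect_equal(sum(lw$weights$smoke), 1)
})
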