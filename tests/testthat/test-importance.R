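test_that("OLS recovers an exact linear signal with R^2 = 1", {
  set.seed(1)
  X <- matrix(rnorm(100), 20, 5)
  beta <- c(1, -2, 0.5, 3, -1)
  y <- 2 + drop(X %*% beta)
  fit <- fit_linear_model(X, y)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
})

test_that("null-response R^2 is near p/n", {
  set.seed(2)
  X <- matrix(rnorm(1e4 * 5), 1e4, 5)
  fit <- fit_linear_model(X, rnorm(1e4))
  expect_lt(fit$r2, 0.01)
})

test_that("rank deficiency is rejected", {
  set.seed(3)
  X <- cbind(rnorm(30), rep(1, 30))  # constant column aliases the intercept
  expect_error(fit_linear_model(X, rnorm(30)), "rank")
})

test_that("a single unit receives the whole R^2", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(1, 0.5)) + rnorm(30)
  sh <- lmg(X, y, list(all = c("a", "b")))
  expect_equal(unname(sh), fit_linear_model(X, y)$r2, tolerance = 1e-12)
})

test_that("empirically orthogonal units get their squared correlation", {
  set.seed(5)
  n <- 40
  a <- rnorm(n)
  b <- rnorm(n)
  a <- a - mean(a)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)      # exactly uncorrelated with a
  X <- cbind(a = a, b = b)
  y <- a + 0.5 * b + rnorm(n)
  sh <- lmg(X, y, list(a = "a", b = "b"))
  expect_equal(unname(sh["a"]), cor(a, y)^2, tolerance = 1e-10)
  expect_equal(unname(sh["b"]), cor(b, y)^2, tolerance = 1e-10)
})

test_that("the two-unit case matches the hand-enumerated formula", {
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  X[, 2] <- X[, 2] + 0.8 * X[, 1]
  y <- drop(X %*% c(1, 1)) + rnorm(40)
  r2 <- function(cols) fit_linear_model(X[, cols, drop = FALSE], y)$r2
  expected_a <- 0.5 * (r2("a") + (r2(c("a", "b")) - r2("b")))
  sh <- lmg(X, y, list(a = "a", b = "b"))
  expect_equal(unname(sh["a"]), expected_a, tolerance = 1e-10)
})

test_that("subset-sum LMG equals the all-orderings brute force", {
  for (p in 2:6) {
    fx <- random_lmg_fixture(p, seed = 100 + p)
    fast <- lmg(fx$X, fx$y, fx$units)
    slow <- lmg_bruteforce(fx$X, fx$y, fx$units)
    expect_equal(fast, slow, tolerance = 1e-10)
    expect_true(all(fast >= 0))
    expect_equal(sum(fast), fit_linear_model(fx$X, fx$y)$r2,
                 tolerance = 1e-10)
  }
})

test_that("shares are equivariant under unit relabeling", {
  fx <- random_lmg_fixture(4, seed = 7)
  sh <- lmg(fx$X, fx$y, fx$units)
  perm <- c(3, 1, 4, 2)
  sh_perm <- lmg(fx$X, fx$y, fx$units[perm])
  expect_equal(unname(sh_perm), unname(sh[perm]), tolerance = 1e-12)
})

test_that("duplicated units share equally through the pseudoinverse path", {
  set.seed(8)
  x <- rnorm(30)
  y <- x + rnorm(30)
  X <- cbind(a = x, b = x)
  sh <- lmg_bruteforce(X, y, list(a = "a", b = "b"))
  expect_equal(unname(sh["a"]), unname(sh["b"]), tolerance = 1e-10)
  expect_equal(sum(sh), cor(x, y)^2, tolerance = 1e-10)
})

test_that("merging two units equals the merged-unit computation", {
  fx <- random_lmg_fixture(4, seed = 9)
  merged_units <- c(list(m = unlist(fx$units[1:2], use.names = FALSE)),
                    fx$units[3:4])
  by_lmg <- lmg(fx$X, fx$y, merged_units)
  by_oracle <- lmg_bruteforce(fx$X, fx$y, merged_units)
  expect_equal(by_lmg, by_oracle, tolerance = 1e-10)
})

test_that("the unit-count enumeration bounds are enforced", {
  fx <- random_lmg_fixture(3, seed = 10)
  too_many <- as.list(seq_len(21))
  expect_error(lmg(matrix(rnorm(630), 30, 21), rnorm(30), too_many), "20")
  expect_error(lmg_bruteforce(matrix(rnorm(240), 30, 8), rnorm(30),
                              as.list(1:8)), "7")
})
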