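# fixtures are built in code; no data files

derive_seed_ref <- rscontrib:::derive_seed

# small cohort with 1 outcome, 2 singles, 2 categories
toy_design <- function() {
  study_design(
    outcome = "y",
    singles = c("age", "ses_med", "ses_high"),
    categories = list(air = c("no2", "nox", "pm"),
                      smoke = c("current", "pack")),
    var_types = c(current = "binary"),
    single_groups = list(SES = c("ses_med", "ses_high")))
}

toy_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  no2 <- rnorm(n)
  data.frame(
    age = rnorm(n, 70, 3),
    ses_med = rbinom(n, 1, 0.5),
    ses_high = rbinom(n, 1, 0.3),
    no2 = no2,
    nox = 0.7 * no2 + rnorm(n, sd = sqrt(1 - 0.49)),
    pm = rnorm(n),
    current = rbinom(n, 1, 0.2),
    pack = rnorm(n, 4, 10),
    y = rnorm(n))
}

# the public ridge objective; independent oracle via a generic numerical
# minimizer (BFGS with analytic gradient)
ridge_objective <- function(par, X, y, penalty, lambda) {
  g0 <- par[1]
  g <- par[-1]
  r <- y - g0 - drop(X %*% g)
  sum(r^2) / (2 * nrow(X)) + lambda * sum(penalty * g^2)
}

ridge_gradient <- function(par, X, y, penalty, lambda) {
  g0 <- par[1]
  g <- par[-1]
  r <- y - g0 - drop(X %*% g)
  c(-sum(r) / nrow(X), -drop(crossprod(X, r)) / nrow(X) + 2 * lambda * penalty * g)
}

optim_ridge <- function(X, y, penalty, lambda) {
  f <- function(par) {
    val <- ridge_objective(par, X, y, penalty, lambda)
    attr(val, "gradient") <- ridge_gradient(par, X, y, penalty, lambda)
    val
  }
  par <- rep(0, ncol(X) + 1)
  for (i in 1:3) {  # restarts polish the quadratic to machine precision
    fit <- stats::nlm(f, par, gradtol = 1e-14, steptol = 1e-14,
                      iterlim = 2000)
    par <- fit$estimate
  }
  list(intercept = par[1], coefficients = par[-1])
}

random_ridge_problem <- function(n = 30, p = 12, n_unpen = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X[, seq_len(p - 1)] <- X[, seq_len(p - 1)] + 0.5 * X[, p]  # correlated
  beta <- rnorm(p, sd = 0.5)
  y <- drop(X %*% beta) + rnorm(n)
  ridge_problem(y, X, c(rep(0, n_unpen), rep(1, p - n_unpen)))
}

# random regression fixture with unit structure; some units multi-column
random_lmg_fixture <- function(p_units, seed, n = 50) {
  set.seed(seed)
  sizes <- sample(1:2, p_units, replace = TRUE)
  p <- sum(sizes)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  y <- drop(X %*% rnorm(p, sd = 0.6)) + rnorm(n)
  stopv <- cumsum(sizes)
  startv <- c(1, utils::head(stopv, -1) + 1)
  units <- lapply(seq_len(p_units), function(u) startv[u]:stopv[u])
  names(units) <- paste0("u", seq_len(p_units))
  list(X = X, y = y, units = units)
}
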