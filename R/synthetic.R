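# Synthetic cohorts with the statistical structure the method assumes:
# block-correlated mixed-type predictors from a Gaussian copula, an outcome
# generated by a linear model on the raw predictor scale, and an analytic
# ground-truth variance decomposition from the implied covariance matrix.
#
# All dependence is specified on the latent Gaussian scale. Continuous
# variables are linear in their latent (so realized correlations equal the
# latent ones); binary and SNP variables are monotone threshold functions of
# their latent, which attenuates realized correlations relative to the latent
# block correlation rho_k.

# ---- variable specs ---------------------------------------------------------

norm_var_spec <- function(spec, where) {
  if (is.null(spec$name)) stop("a variable spec in ", where, " lacks a name")
  spec$type <- spec$type %||% "continuous"
  spec$effect <- spec$effect %||% 0
  switch(spec$type,
    continuous = {
      spec$mean <- spec$mean %||% 0
      spec$sd <- spec$sd %||% 1
      if (spec$sd <= 0) stop("sd must be positive for '", spec$name, "'")
    },
    binary = {
      if (is.null(spec$prevalence) || spec$prevalence <= 0 ||
          spec$prevalence >= 1)
        stop("binary '", spec$name, "' needs prevalence in (0,1)")
    },
    snp = {
      if (is.null(spec$maf) || spec$maf <= 0 || spec$maf >= 1)
        stop("snp '", spec$name, "' needs maf in (0,1)")
    },
    stop("unknown type '", spec$type, "' for '", spec$name, "' in ", where))
  spec
}

# thresholds of the monotone step function x(z) = #{t : z > t}; NULL for
# continuous (linear) variables
var_thresholds <- function(spec) {
  switch(spec$type,
    continuous = NULL,
    binary = stats::qnorm(1 - spec$prevalence),
    snp = c(stats::qnorm((1 - spec$maf)^2),
            stats::qnorm(1 - spec$maf^2)))
}

var_marginal_mean <- function(spec) {
  switch(spec$type,
    continuous = spec$mean,
    binary = spec$prevalence,
    snp = 2 * spec$maf)
}

var_marginal_var <- function(spec) {
  switch(spec$type,
    continuous = spec$sd^2,
    binary = spec$prevalence * (1 - spec$prevalence),
    snp = 2 * spec$maf * (1 - spec$maf))
}

# upper orthant probability P(Z1 > a, Z2 > b), corr(Z1,Z2) = rho, |rho| < 1
orthant2 <- function(a, b, rho) {
  if (rho == 0) return(stats::pnorm(a, lower.tail = FALSE) *
                         stats::pnorm(b, lower.tail = FALSE))
  f <- function(z)
    stats::dnorm(z) * stats::pnorm((rho * z - b) / sqrt(1 - rho^2))
  stats::integrate(f, a, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# covariance of two distinct generated variables with latent correlation rho
cov_pair <- function(si, sj, rho) {
  if (rho == 0) return(0)
  ti <- var_thresholds(si)
  tj <- var_thresholds(sj)
  if (is.null(ti) && is.null(tj)) return(si$sd * sj$sd * rho)
  if (is.null(ti)) return(si$sd * rho * sum(stats::dnorm(tj)))
  if (is.null(tj)) return(sj$sd * rho * sum(stats::dnorm(ti)))
  total <- 0
  for (t in ti) for (s in tj)
    total <- total + orthant2(t, s, rho) -
      stats::pnorm(t, lower.tail = FALSE) * stats::pnorm(s, lower.tail = FALSE)
  total
}

# ---- model constructor ------------------------------------------------------

#' Specify a synthetic cohort model
#'
#' Defines a generative model for a participant-by-variable table:
#' single predictors with an optional latent correlation matrix, risk-factor
#' categories as compound-symmetric latent blocks (within-block correlation
#' `rho`), mixed marginal types (continuous, binary, SNP 0/1/2), and an
#' outcome `y = sum_j effect_j * x_j + N(0, noise_sd^2)` on the raw predictor
#' scale, standardized to a z-score after generation.
#'
#' @param n number of participants (>= 2).
#' @param singles list of single-predictor specs; each a list with `name`,
#'   `type` (`"continuous"`, `"binary"`, `"snp"`), marginal parameters
#'   (`mean`/`sd`, `prevalence`, or `maf`), optional `effect` (default 0) and
#'   optional `group` (single-group label for the importance decomposition).
#' @param categories named list of category blocks; each a list with `rho`
#'   (within-block latent correlation in `[0, 1)`) and `members` (list of
#'   specs as above).
#' @param noise_sd residual standard deviation of the outcome model.
#' @param single_cor optional latent correlation matrix among the singles
#'   (default identity); must be positive definite.
#' @return object of class `synthetic_model`.
#' @seealso [generate_cohort()], [true_contributions()], [salia_template()]
#' @export
synthetic_model <- function(n, singles = list(), categories = list(),
                            noise_sd = 1, single_cor = NULL) {
  stopifnot(n >= 2, noise_sd >= 0)
  singles <- lapply(singles, norm_var_spec, where = "singles")
  if (length(categories) && is.null(names(categories)))
    stop("'categories' must be a named list")
  categories <- lapply(stats::setNames(names(categories), names(categories)),
                       function(k) {
    blk <- categories[[k]]
    blk$rho <- blk$rho %||% 0
    if (blk$rho < 0 || blk$rho >= 1)
      stop("category '", k, "': rho must lie in [0, 1)")
    if (length(blk$members) < 1L)
      stop("category '", k, "' needs at least one member")
    blk$members <- lapply(blk$members, norm_var_spec, where = k)
    blk
  })
  if (!is.null(single_cor)) {
    single_cor <- as.matrix(single_cor)
    stopifnot(nrow(single_cor) == length(singles),
              ncol(single_cor) == length(singles))
    ok <- tryCatch({ chol(single_cor); TRUE }, error = function(e) FALSE)
    if (!ok) stop("single_cor is not positive definite")
  }
  structure(list(n = as.integer(n), singles = singles,
                 categories = categories, noise_sd = noise_sd,
                 single_cor = single_cor),
            class = "synthetic_model")
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat("Synthetic cohort model: n =", x$n, "\n")
  cat("  singles:", length(x$singles), " noise_sd:", x$noise_sd, "\n")
  for (k in names(x$categories))
    cat(sprintf("  category %-12s m = %d, rho = %.2f\n", k,
                length(x$categories[[k]]$members), x$categories[[k]]$rho))
  invisible(x)
}

# all predictor specs in canonical order (singles, then members by category)
model_specs <- function(model) {
  c(model$singles,
    unlist(lapply(model$categories, `[[`, "members"), recursive = FALSE))
}

# the study design implied by a synthetic model
model_design <- function(model, outcome = "y") {
  specs <- model_specs(model)
  nm <- vapply(specs, `[[`, character(1), "name")
  types <- vapply(specs, `[[`, character(1), "type")
  singles <- vapply(model$singles, `[[`, character(1), "name")
  groups <- list()
  for (sp in model$singles)
    if (!is.null(sp$group))
      groups[[sp$group]] <- c(groups[[sp$group]], sp$name)
  study_design(
    outcome = outcome,
    singles = singles,
    categories = lapply(model$categories,
                        function(b) vapply(b$members, `[[`, character(1),
                                           "name")),
    var_types = stats::setNames(types, nm)[types != "continuous"],
    single_groups = groups)
}

# ---- generation -------------------------------------------------------------

draw_block <- function(n, k, rho_mat) {
  Z <- matrix(stats::rnorm(n * k), n, k)
  if (!is.null(rho_mat)) Z <- Z %*% chol(rho_mat)
  Z
}

transform_latent <- function(z, spec) {
  switch(spec$type,
    continuous = spec$mean + spec$sd * z,
    binary = as.numeric(z > stats::qnorm(1 - spec$prevalence)),
    snp = stats::qbinom(stats::pnorm(z), 2L, spec$maf))
}

#' Generate a synthetic cohort
#'
#' Draws latent Gaussians block by block (singles block, then each category's
#' compound-symmetric block), transforms them to the declared marginals
#' (linear for continuous, quantile thresholding for binary and SNP), builds
#' the outcome from the linear model plus Gaussian noise, and standardizes
#' the outcome to a z-score. Identical `(model, seed)` give byte-identical
#' tables.
#'
#' @param model a [synthetic_model()].
#' @param seed integer seed.
#' @param outcome name for the outcome column (default `"y"`).
#' @return list with `data` (data frame) and `design` (the matching
#'   [study_design()]).
#' @export
generate_cohort <- function(model, seed, outcome = "y") {
  stopifnot(inherits(model, "synthetic_model"))
  set.seed(derive_seed(seed, 11L))
  n <- model$n
  cols <- list()

  if (length(model$singles)) {
    Z <- draw_block(n, length(model$singles), model$single_cor)
    for (j in seq_along(model$singles)) {
      sp <- model$singles[[j]]
      cols[[sp$name]] <- transform_latent(Z[, j], sp)
    }
  }
  for (k in names(model$categories)) {
    blk <- model$categories[[k]]
    m <- length(blk$members)
    R <- matrix(blk$rho, m, m)
    diag(R) <- 1
    Z <- draw_block(n, m, if (m > 1L) R else NULL)
    for (j in seq_len(m)) {
      sp <- blk$members[[j]]
      cols[[sp$name]] <- transform_latent(Z[, j], sp)
    }
  }

  specs <- model_specs(model)
  effects <- vapply(specs, `[[`, numeric(1), "effect")
  X <- do.call(cbind, cols)
  y_raw <- drop(X %*% effects) + stats::rnorm(n, 0, model$noise_sd)
  y <- (y_raw - mean(y_raw)) / stats::sd(y_raw)

  data <- as.data.frame(cols)
  data[[outcome]] <- y
  list(data = data, design = model_design(model, outcome))
}

# ---- analytic ground truth --------------------------------------------------

# implied covariance matrix of the generated predictors
implied_covariance <- function(model) {
  specs <- model_specs(model)
  p <- length(specs)
  block <- c(rep(0L, length(model$singles)),
             rep(seq_along(model$categories),
                 vapply(model$categories, function(b) length(b$members),
                        integer(1))))
  Sigma <- matrix(0, p, p)
  nm <- vapply(specs, `[[`, character(1), "name")
  dimnames(Sigma) <- list(nm, nm)
  for (i in seq_len(p)) {
    Sigma[i, i] <- var_marginal_var(specs[[i]])
    if (i == p) next
    for (j in (i + 1L):p) {
      rho <- 0
      if (block[i] == 0L && block[j] == 0L) {
        if (!is.null(model$single_cor)) rho <- model$single_cor[i, j]
      } else if (block[i] == block[j]) {
        rho <- model$categories[[block[i]]]$rho
      }
      Sigma[i, j] <- Sigma[j, i] <- cov_pair(specs[[i]], specs[[j]], rho)
    }
  }
  Sigma
}

#' Population LMG shares and R-squared of a synthetic model
#'
#' Computes the ground-truth variance decomposition analytically from the
#' model's implied covariance matrix: subset R-squareds follow from
#' covariance algebra and the LMG average is taken over regressor units,
#' treating each category's best linear combination (all member columns) as
#' one unit and each single predictor (or declared single group) as one
#' unit. Shares are nonnegative and sum to the population R-squared; because
#' the outcome is standardized to a z-score, shares are unaffected by that
#' scaling.
#'
#' @param model a [synthetic_model()].
#' @return list with `shares` (named per-unit vector), `r2` (their sum) and
#'   `sigma` (the implied predictor covariance matrix).
#' @export
true_contributions <- function(model) {
  stopifnot(inherits(model, "synthetic_model"))
  Sigma <- implied_covariance(model)
  specs <- model_specs(model)
  beta <- vapply(specs, `[[`, numeric(1), "effect")
  sxy <- drop(Sigma %*% beta)
  vy <- drop(crossprod(beta, sxy)) + model$noise_sd^2
  if (vy <= 0) stop("implied outcome variance is not positive")

  design <- model_design(model)
  units <- list()
  grouped <- unlist(design$single_groups, use.names = FALSE)
  for (s in setdiff(design$singles, grouped)) units[[s]] <- s
  for (g in names(design$single_groups))
    units[[g]] <- design$single_groups[[g]]
  for (k in names(design$categories)) units[[k]] <- design$categories[[k]]

  idx_units <- lapply(units, function(u) match(u, rownames(Sigma)))
  shares <- lmg_from_moments(Sigma, sxy, vy, idx_units)
  list(shares = shares, r2 = sum(shares), sigma = Sigma)
}

# ---- packaged templates -----------------------------------------------------

#' Synthetic template of an elderly-women cohort (lung-function layout)
#'
#' A packaged [synthetic_model()] whose marginal means, SDs and prevalences
#' follow the descriptive statistics of the lung-function analysis sample of
#' an elderly German female cohort (n = 510): single predictors age, height
#' and two socio-economic-status dummies (grouped as one unit), and risk
#' factor categories genetic (SNPs), obesity, smoking and air pollution.
#' This is a synthetic emulation for testing and documentation, not cohort
#' data; category effects are calibrated internally so that the analytic
#' population contributions roughly mirror the published ranking for
#' lung-function outcomes (genetic largest, then smoking and obesity) with a
#' population R-squared near 0.22.
#'
#' The SNP block defaults to 20 members for desk-scale runs; set
#' `n_snps = 278` for the full-size genetic category.
#'
#' @param n participants (default 510).
#' @param n_snps number of SNP members of the genetic category (default 20).
#' @return a `synthetic_model`.
#' @export
salia_template <- function(n = 510, n_snps = 20) {
  singles <- list(
    list(name = "age", mean = 73.52, sd = 2.99),
    list(name = "height", mean = 162.83, sd = 5.76),
    list(name = "ses_med", type = "binary", prevalence = 0.488, group = "SES"),
    list(name = "ses_high", type = "binary", prevalence = 0.337, group = "SES"))
  single_cor <- diag(4)
  single_cor[3, 4] <- single_cor[4, 3] <- -0.9  # dummies nearly exclusive

  mafs <- seq(0.1, 0.45, length.out = n_snps)
  categories <- list(
    genetic = list(rho = 0.1, members = lapply(seq_len(n_snps), function(j)
      list(name = sprintf("snp%02d", j), type = "snp", maf = mafs[j]))),
    obesity = list(rho = 0.5, members = list(
      list(name = "bmi_fu1", mean = 26.66, sd = 3.66),
      list(name = "bmi_fu2", mean = 27.29, sd = 4.34),
      list(name = "low_activity", type = "binary", prevalence = 0.602))),
    smoking = list(rho = 0.3, members = list(
      list(name = "current_smoking", type = "binary", prevalence = 0.024),
      list(name = "former_smoking", type = "binary", prevalence = 0.167),
      list(name = "ets_work", type = "binary", prevalence = 0.424),
      list(name = "ets_home", type = "binary", prevalence = 0.339),
      list(name = "packyears", mean = 3.83, sd = 12.74))),
    air_pollution = list(rho = 0.6, members = list(
      list(name = "urban_residence", type = "binary", prevalence = 0.512),
      list(name = "no2", mean = 37.21, sd = 11.16),
      list(name = "nox", mean = 69.17, sd = 31.93),
      list(name = "pm10", mean = 48.98, sd = 7.38),
      list(name = "pm25", mean = 32.56, sd = 4.78),
      list(name = "pm_coarse", mean = 17.42, sd = 3.91),
      list(name = "pm25_abs", mean = 2.71, sd = 0.92),
      list(name = "traffic_load", mean = 839.51, sd = 2200.63),
      list(name = "inv_dist_major", mean = 0.01, sd = 0.02))))

  # target population variance shares (outcome variance normalized to 1)
  share_single <- c(age = 0.003, height = 0.004)
  share_group <- c(SES = 0.008)
  share_cat <- c(genetic = 0.11, obesity = 0.04, smoking = 0.05,
                 air_pollution = 0.005)

  model <- synthetic_model(n, singles, categories, noise_sd = 1,
                           single_cor = single_cor)
  calibrate_effects(model, share_single, share_group, share_cat)
}

# set equal within-unit effects so each unit contributes the target share of
# a unit-variance outcome, and noise_sd absorbs the rest
calibrate_effects <- function(model, share_single = NULL, share_group = NULL,
                              share_cat = NULL) {
  Sigma <- implied_covariance(model)
  nm <- rownames(Sigma)
  set_equal_effect <- function(vars, v_target) {
    idx <- match(vars, nm)
    tot <- sum(Sigma[idx, idx])
    if (tot <= 0) stop("unit covariance sums to a nonpositive value")
    sqrt(v_target / tot)
  }
  for (i in seq_along(model$singles)) {
    sp <- model$singles[[i]]
    if (!is.null(share_single) && sp$name %in% names(share_single))
      model$singles[[i]]$effect <-
        set_equal_effect(sp$name, share_single[[sp$name]])
  }
  if (!is.null(share_group)) {
    for (g in names(share_group)) {
      vars <- vapply(Filter(function(sp) identical(sp$group, g),
                            model$singles), `[[`, character(1), "name")
      b <- set_equal_effect(vars, share_group[[g]])
      for (i in seq_along(model$singles))
        if (identical(model$singles[[i]]$group, g))
          model$singles[[i]]$effect <- b
    }
  }
  if (!is.null(share_cat)) {
    for (k in names(share_cat)) {
      vars <- vapply(model$categories[[k]]$members, `[[`, character(1), "name")
      b <- set_equal_effect(vars, share_cat[[k]])
      for (j in seq_along(model$categories[[k]]$members))
        model$categories[[k]]$members[[j]]$effect <- b
    }
  }
  total <- sum(share_single, share_group, share_cat)
  if (total >= 1) stop("target shares sum to >= 1")
  model$noise_sd <- sqrt(1 - total)
  model
}

#' Synthetic model with prescribed population LMG shares
#'
#' Builds a cohort model of mutually independent continuous category blocks
#' (plus inert single predictors) whose analytic population LMG shares equal
#' `shares` exactly: members have unit variance and within-block correlation
#' `rho`, the per-member effect is `sqrt(share / (m * (1 + (m-1) * rho)))`,
#' and `noise_sd` completes the outcome variance to 1. Because the blocks
#' are independent, each unit's LMG share equals its marginal R-squared
#' contribution. Useful for parameter-recovery and null-calibration studies
#' (`shares = c(0, 0, 0)` gives a pure-noise cohort).
#'
#' @param shares numeric vector of target per-category shares (sum < 1).
#' @param n participants (default 2000).
#' @param m members per category (default 4).
#' @param rho within-block latent correlation (default 0.5).
#' @param n_singles number of effect-free single predictors (default 2).
#' @return a `synthetic_model` with categories `cat1`, `cat2`, ...
#' @export
synthetic_model_shares <- function(shares, n = 2000, m = 4, rho = 0.5,
                                   n_singles = 2) {
  stopifnot(all(shares >= 0), sum(shares) < 1)
  singles <- lapply(seq_len(n_singles), function(j)
    list(name = paste0("s", j)))
  categories <- list()
  for (k in seq_along(shares)) {
    b <- sqrt(shares[k] / (m * (1 + (m - 1) * rho)))
    categories[[paste0("cat", k)]] <- list(rho = rho, members = lapply(
      seq_len(m), function(j)
        list(name = sprintf("x%d_%d", k, j), effect = b)))
  }
  synthetic_model(n, singles, categories,
                  noise_sd = sqrt(1 - sum(shares)))
}
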