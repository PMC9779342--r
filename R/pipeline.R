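#' Analysis configuration
#'
#' Collects the tuning knobs of the full pipeline. Defaults follow the
#' method's published settings: a 60/40 train/test split, tenfold
#' cross-validation for the ridge penalty repeated twenty times, and
#' percentile summaries at the 95% level. `B` defaults to 200 (use 500 for
#' smaller predictor sets if runtime allows).
#'
#' @param B number of bootstrap replicates (replicate 0 is the original
#'   data set).
#' @param train_fraction training proportion, strictly in (0, 1).
#' @param cv_folds cross-validation folds for lambda selection.
#' @param cv_repeats number of fold re-randomizations whose coefficient
#'   estimates are averaged.
#' @param n_lambda,lambda_min_ratio lambda grid: length and smallest/largest
#'   ratio.
#' @param ci_level percentile confidence level.
#' @param seed master seed; every replicate, split and fold assignment draws
#'   from a stream derived from it.
#' @param standardize_on `"train"` (default): standardization statistics are
#'   computed on each replicate's training sample and frozen for its test
#'   sample, preventing leakage. `"full"`: the original table is standardized
#'   once before bootstrapping.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(B = 200, train_fraction = 0.6, cv_folds = 10,
                            cv_repeats = 20, n_lambda = 100,
                            lambda_min_ratio = 1e-4, ci_level = 0.95,
                            seed = 1, standardize_on = c("train", "full")) {
  stopifnot(B >= 1, train_fraction > 0, train_fraction < 1,
            cv_folds >= 2, cv_repeats >= 1, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            ci_level > 0, ci_level < 1)
  structure(list(B = as.integer(B), train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 ci_level = ci_level, seed = as.integer(seed),
                 standardize_on = match.arg(standardize_on)),
            class = "analysis_config")
}

# regressor units of the final test-sample model: plain singles, single
# groups, and one unit per risk score column
final_units <- function(design) {
  units <- list()
  grouped <- unlist(design$single_groups, use.names = FALSE)
  for (s in setdiff(design$singles, grouped)) units[[s]] <- s
  for (g in names(design$single_groups)) units[[g]] <- design$single_groups[[g]]
  for (k in names(design$categories)) units[[k]] <- paste0("RS_", k)
  units
}

#' Run one bootstrap replicate of the full pipeline
#'
#' Resample (identity for replicate 0) -> split 60/40 -> standardize (frozen
#' training statistics, unless the configuration standardizes the full table
#' up front) -> learn category weights on the training sample -> compose and
#' IQR-scale risk scores on the test sample -> OLS fit and LMG decomposition
#' on the test sample. Fully reproducible from `(config$seed, index)`.
#'
#' @param table cohort table (complete cases).
#' @param design a validated [study_design()].
#' @param config an [analysis_config()].
#' @param index replicate index, `0 .. B-1`.
#' @return list with `index`, `coefficients` (incl. intercept), `r2`,
#'   `shares`, `iqr`, `weights`, `lambdas` and `flags`.
#' @export
run_single_replicate <- function(table, design, config, index) {
  rep_seed <- derive_seed(config$seed, 1000L, index)
  flags <- character()

  tab <- bootstrap_resample(table, index, config$seed)
  parts <- split_train_test(tab, config$train_fraction, rep_seed)
  train <- parts$train
  test <- parts$test

  if (config$standardize_on == "train") {
    stats <- standardization_stats(train, design)
    train <- standardize(train, design, stats)
    test <- standardize(test, design, stats)
    if (any(stats$degenerate))
      flags <- c(flags, paste0("degenerate_column:",
                               stats$variable[stats$degenerate]))
  }

  learned <- learn_category_weights(train, design, config, seed = rep_seed)
  flags <- unique(c(flags, learned$flags))

  scores <- list()
  iqr <- numeric(0)
  for (k in names(design$categories)) {
    z <- compute_risk_score(test, learned$weights[[k]])
    sc <- iqr_scale(z, category = k)          # errors on zero IQR -> flagged
    scores[[paste0("RS_", k)]] <- sc$scaled
    iqr[k] <- sc$iqr
  }

  Xtest <- cbind(as.matrix(test[, design$singles, drop = FALSE]),
                 do.call(cbind, scores))
  colnames(Xtest) <- c(design$singles, names(scores))
  fit <- fit_linear_model(Xtest, test[[design$outcome]])
  shares <- lmg(Xtest, test[[design$outcome]], final_units(design))

  list(index = index,
       coefficients = c("(Intercept)" = fit$intercept, fit$coefficients),
       r2 = fit$r2, shares = shares, iqr = iqr,
       weights = learned$weights, lambdas = learned$lambdas, flags = flags)
}

#' Estimate relative contributions of risk-factor categories
#'
#' The main fitting function. Runs the two-step method over `B` bootstrap
#' replicates of the cohort: each replicate learns risk-score weights by
#' penalty-factor ridge regression on a training split, composes IQR-scaled
#' risk scores on the test split, fits the linear model over risk scores and
#' single predictors, and decomposes its R-squared with the LMG measure.
#' Results are aggregated as bootstrap medians, percentile confidence
#' intervals and sign-crossing p-values.
#'
#' Replicates that degenerate (zero risk-score IQR, rank-deficient test
#' design) are flagged and excluded from the summaries; if more than half of
#' the replicates fail the run aborts.
#'
#' @param data cohort data frame; rows with missing analysis variables are
#'   dropped (complete-case analysis, with a message).
#' @param design a [study_design()] describing the variable roles.
#' @param config an [analysis_config()]; alternatively pass individual knobs
#'   through `...` (e.g. `B = 100, seed = 7`).
#' @param ... arguments forwarded to [analysis_config()] when `config` is
#'   missing.
#' @return an object of class `rscontrib`; see [summary.rscontrib()].
#' @examples
#' mod <- synthetic_model_shares(c(0.12, 0.06), n = 300, m = 3)
#' cohort <- generate_cohort(mod, seed = 1)
#' fit <- rscontrib(cohort$data, cohort$design, B = 3, cv_repeats = 2, seed = 1)
#' fit
#' @export
rscontrib <- function(data, design, config = NULL, ...) {
  if (is.null(config)) config <- analysis_config(...)
  stopifnot(inherits(config, "analysis_config"))
  design <- validate_design(design, data)
  data <- drop_incomplete(data, design)
  if (nrow(data) < 10L) stop("fewer than 10 complete cases")

  if (config$standardize_on == "full") {
    stats <- standardization_stats(data, design)
    data <- standardize(data, design, stats)
  }

  replicates <- vector("list", config$B)
  for (b in seq_len(config$B) - 1L) {
    replicates[[b + 1L]] <- tryCatch(
      run_single_replicate(data, design, config, b),
      error = function(e)
        list(index = b, failed = TRUE,
             flags = paste0("failed:", conditionMessage(e))))
  }
  failed <- vapply(replicates, function(r) isTRUE(r$failed), logical(1))
  if (mean(failed) > 0.5)
    stop("more than half of the bootstrap replicates degenerated; ",
         "first failure: ", replicates[[which(failed)[1]]]$flags[1])

  out <- structure(
    list(call = match.call(), design = design, config = config,
         n = nrow(data), replicates = replicates, failed = failed),
    class = "rscontrib")
  out$summary <- bootstrap_summary(out, config$ci_level)
  out
}

#' Summarize a bootstrap result
#'
#' Medians, percentile confidence bounds (type-7 interpolation, matching the
#' quantile convention used for IQR scaling) and, for regression
#' coefficients, two-sided bootstrap p-values `2 * min(f+, f-)` where
#' `f+`/`f-` are the fractions of replicate coefficients `>= 0` / `<= 0`,
#' floored at the minimum attainable `2 / B_effective`. Failed replicates
#' are excluded; replicate 0 (the original data) is included.
#'
#' @param object an `rscontrib` fit.
#' @param ci_level confidence level (default: from the fit's config).
#' @return list of data frames `contributions`, `coefficients`, `r2`,
#'   `weights`, plus `n_failed`.
#' @export
bootstrap_summary <- function(object, ci_level = object$config$ci_level) {
  reps <- object$replicates[!object$failed]
  if (!length(reps)) stop("no usable replicates")
  alpha <- 1 - ci_level
  probs <- c(alpha / 2, 1 - alpha / 2)
  B_eff <- length(reps)

  share_mat <- vapply(reps, `[[`, reps[[1]]$shares, "shares")
  if (is.null(dim(share_mat)))
    share_mat <- matrix(share_mat, nrow = 1,
                        dimnames = list(names(reps[[1]]$shares), NULL))
  contributions <- data.frame(
    predictor = rownames(share_mat),
    median = apply(share_mat, 1L, stats::median),
    lower = apply(share_mat, 1L, quantile7, probs = probs[1]),
    upper = apply(share_mat, 1L, quantile7, probs = probs[2]),
    row.names = NULL)
  contributions <- contributions[order(-contributions$median), ]

  coef_mat <- vapply(reps, `[[`, reps[[1]]$coefficients, "coefficients")
  pval <- apply(coef_mat, 1L, function(x)
    min(1, max(2 * min(mean(x >= 0), mean(x <= 0)), 2 / B_eff)))
  coefficients <- data.frame(
    term = rownames(coef_mat),
    median = apply(coef_mat, 1L, stats::median),
    lower = apply(coef_mat, 1L, quantile7, probs = probs[1]),
    upper = apply(coef_mat, 1L, quantile7, probs = probs[2]),
    p_value = pval, row.names = NULL)

  r2_vec <- vapply(reps, `[[`, numeric(1), "r2")
  r2 <- data.frame(median = stats::median(r2_vec),
                   lower = quantile7(r2_vec, probs[1]),
                   upper = quantile7(r2_vec, probs[2]))

  wt <- list()
  for (k in names(object$design$categories)) {
    W <- vapply(reps, function(r) as.numeric(r$weights[[k]]),
                numeric(length(object$design$categories[[k]])))
    if (is.null(dim(W))) W <- matrix(W, 1)
    wt[[k]] <- data.frame(category = k,
                          member = object$design$categories[[k]],
                          median_weight = apply(W, 1L, stats::median),
                          row.names = NULL)
  }
  weights <- do.call(rbind, c(wt, list(make.row.names = FALSE)))

  list(contributions = contributions, coefficients = coefficients, r2 = r2,
       weights = weights, n_failed = sum(object$failed), ci_level = ci_level)
}
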