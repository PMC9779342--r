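#' Standardization statistics from a reference sample
#'
#' Computes per-variable means and standard deviations (denominator n-1) on a
#' reference sample, for every predictor flagged `standardize = TRUE` in the
#' design (all predictors except SNP variables by default; the outcome is
#' never standardized). The frozen statistics are later applied unchanged to
#' other samples, so standardizing the training sample and then the test
#' sample with the same object cannot leak test information.
#'
#' A column that is constant in the reference sample (possible for rare
#' binary indicators under bootstrap resampling) gets `sd = NA` and is marked
#' degenerate; [standardize()] maps it to all zeros.
#'
#' @param table reference sample (data frame).
#' @param design a validated [study_design()].
#' @return object of class `standardization_stats`: data frame with columns
#'   `variable`, `mean`, `sd`, `degenerate`.
#' @export
standardization_stats <- function(table, design) {
  vars <- names(design$standardize)[design$standardize]
  mu <- vapply(vars, function(v) mean(table[[v]]), numeric(1))
  sdv <- vapply(vars, function(v) stats::sd(table[[v]]), numeric(1))
  deg <- !is.finite(sdv) | sdv == 0
  sdv[deg] <- NA_real_
  structure(
    data.frame(variable = vars, mean = mu, sd = sdv, degenerate = deg,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("standardization_stats", "data.frame"))
}

#' Standardize predictors with frozen reference statistics
#'
#' Transforms each flagged column to `(x - mean) / sd` using the reference
#' statistics; SNP columns and the outcome pass through untouched. Degenerate
#' columns (zero reference SD) are set to all zeros and their names attached
#' as attribute `"degenerate"` for replicate-level logging.
#'
#' @param table data frame to transform.
#' @param design a validated [study_design()].
#' @param stats a [standardization_stats()] object.
#' @return the transformed table (same shape), possibly with attribute
#'   `"degenerate"`.
#' @export
standardize <- function(table, design, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  need <- names(design$standardize)[design$standardize]
  missing <- setdiff(need, stats$variable)
  if (length(missing))
    stop("standardization stats missing for: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(stats))) {
    v <- stats$variable[i]
    if (stats$degenerate[i]) {
      table[[v]] <- rep(0, nrow(table))
    } else {
      table[[v]] <- (table[[v]] - stats$mean[i]) / stats$sd[i]
    }
  }
  if (any(stats$degenerate))
    attr(table, "degenerate") <- stats$variable[stats$degenerate]
  table
}

#' Bootstrap resample of a cohort table
#'
#' Replicate 0 is the original data set unchanged; replicates `b >= 1` draw
#' `n` rows with replacement, reproducibly from `(seed, b)`. No cell value is
#' ever invented: every resampled row is an original row.
#'
#' @param table cohort table (data frame).
#' @param b replicate index, `0 .. B-1`.
#' @param seed master seed; each replicate uses its own derived stream.
#' @return a data frame with `nrow(table)` rows.
#' @export
bootstrap_resample <- function(table, b, seed) {
  if (nrow(table) == 0L) stop("cannot resample an empty table")
  stopifnot(b >= 0)
  if (b == 0L) return(table)
  set.seed(derive_seed(seed, 101L, b))
  idx <- sample.int(nrow(table), nrow(table), replace = TRUE)
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random train/test split
#'
#' Partitions the rows uniformly at random (no stratification) into a
#' training part of `round(fraction * n)` rows (ties rounded half away from
#' zero) and a test part holding the rest.
#'
#' @param table data frame, at least 5 rows.
#' @param fraction training proportion, strictly between 0 and 1.
#' @param seed integer seed for the permutation.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(table, fraction, seed) {
  n <- nrow(table)
  stopifnot(fraction > 0, fraction < 1, n >= 5)
  n_train <- as.integer(round_half_up(fraction * n))
  if (n_train < 1L || n_train >= n)
    stop("split would leave an empty training or test sample")
  set.seed(derive_seed(seed, 202L))
  perm <- sample.int(n)
  list(train = table[perm[seq_len(n_train)], , drop = FALSE],
       test  = table[perm[(n_train + 1L):n], , drop = FALSE])
}
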