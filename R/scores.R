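#' Compose a category's risk score in the test sample
#'
#' The raw risk score of category k for participant i is the weighted sum
#' `z_ki = sum_j w_kj * x_kij` over the category's members, evaluated on
#' columns transformed with the training-sample standardization statistics.
#' Because the weights sum to one this is a weighted average.
#'
#' @param table test table (already standardized with frozen training stats).
#' @param weights named numeric weight vector whose names are member columns,
#'   e.g. one element of `learn_category_weights()$weights`.
#' @return numeric vector of raw risk-score values.
#' @export
compute_risk_score <- function(table, weights) {
  missing <- setdiff(names(weights), names(table))
  if (length(missing))
    stop("test table is missing member column(s): ",
         paste(missing, collapse = ", "))
  drop(as.matrix(table[, names(weights), drop = FALSE]) %*% as.numeric(weights))
}

#' Scale a risk score by its interquartile range
#'
#' `z_tilde = z / IQR(z)`, with the IQR computed on the supplied values
#' (the test sample of the current replicate) under the linear-interpolation
#' quantile convention (type 7). After scaling, a regression coefficient on
#' `z_tilde` reads as the outcome change per one-IQR increase of the raw
#' score.
#'
#' @param z raw risk-score values (at least 4).
#' @param category optional category label carried along.
#' @return object of class `risk_score`: list with `category`, `raw`, `iqr`,
#'   `scaled`.
#' @export
iqr_scale <- function(z, category = NULL) {
  stopifnot(length(z) >= 4L)
  iqr <- iqr7(z)
  if (!is.finite(iqr) || iqr <= 0)
    stop("degenerate risk score: interquartile range is zero",
         if (!is.null(category)) paste0(" (category '", category, "')") else "")
  structure(list(category = category, raw = z, iqr = iqr, scaled = z / iqr),
            class = "risk_score")
}
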