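#' @export
print.rscontrib <- function(x, ...) {
  s <- x$summary
  cat("Relative contributions of risk-factor categories (bootstrap)\n")
  cat(sprintf("  n = %d participants, B = %d replicates (%d excluded)\n",
              x$n, x$config$B, s$n_failed))
  cat(sprintf("  overall R^2: %.2f%% [%.2f%%, %.2f%%]\n",
              100 * s$r2$median, 100 * s$r2$lower, 100 * s$r2$upper))
  cat("  top contributions (median, % of variance):\n")
  top <- utils::head(s$contributions, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-16s %6.2f%%  [%.2f%%, %.2f%%]\n", top$predictor[i],
                100 * top$median[i], 100 * top$lower[i], 100 * top$upper[i]))
  invisible(x)
}

#' Summarize an rscontrib fit
#'
#' @param object an `rscontrib` fit.
#' @param ... unused.
#' @return the stored bootstrap summary (see [bootstrap_summary()]), of class
#'   `summary.rscontrib`.
#' @export
summary.rscontrib <- function(object, ...) {
  structure(object$summary, class = "summary.rscontrib")
}

#' @export
print.summary.rscontrib <- function(x, ...) {
  cat(sprintf("Relative contributions (median and %d%% percentile CI)\n",
              round(100 * x$ci_level)))
  tab <- x$contributions
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.2f%%", 100 * v))
  print(tab, row.names = FALSE)
  cat(sprintf("\nOverall R^2: %.2f%% [%.2f%%, %.2f%%]\n",
              100 * x$r2$median, 100 * x$r2$lower, 100 * x$r2$upper))
  cat("\nRegression coefficients (per one-IQR increase for risk scores)\n")
  tab <- x$coefficients
  tab$median <- sprintf("%.3f", tab$median)
  tab$ci <- sprintf("[%.3f, %.3f]", x$coefficients$lower,
                    x$coefficients$upper)
  tab$p <- sprintf("%.3f", x$coefficients$p_value)
  print(tab[, c("term", "median", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Median bootstrap coefficients of an rscontrib fit
#'
#' @param object an `rscontrib` fit.
#' @param ... unused.
#' @return named numeric vector of median coefficients (risk-score
#'   coefficients are per one-IQR increase of the raw score).
#' @export
coef.rscontrib <- function(object, ...) {
  stats::setNames(object$summary$coefficients$median,
                  object$summary$coefficients$term)
}

#' Coefficient plot for an rscontrib fit
#'
#' Dot-and-whisker plot of the bootstrap median regression coefficients with
#' their percentile confidence intervals, in the style of the usual
#' forest-type coefficient figure.
#'
#' @param x an `rscontrib` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rscontrib <- function(x, ...) {
  cf <- x$summary$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  k <- nrow(cf)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cf$median, seq_len(k), yaxt = "n", ylab = "",
                 xlab = "coefficient (outcome change per unit / per IQR)",
                 xlim = range(cf$lower, cf$upper, 0), pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = cf$term, las = 1)
  graphics::segments(cf$lower, seq_len(k), cf$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
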