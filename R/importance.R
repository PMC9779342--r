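# LMG decomposition of R^2 over regressor units.
#
# A "unit" is one or more design-matrix columns treated as a block: each risk
# score is a unit, each plain single predictor is a unit, and grouped dummy
# variables (e.g. the two SES dummies) form one unit. The LMG share of a unit
# is its sequential R^2 increment averaged over all orderings of the units,
# i.e. the Shapley value of R^2 over unit subsets; the shares sum to the
# full-model R^2.

# resolve a units argument (list of column names or indices) to index list
resolve_units <- function(units, X) {
  if (is.null(names(units)))
    names(units) <- paste0("unit", seq_along(units))
  lapply(units, function(u) {
    if (is.character(u)) {
      idx <- match(u, colnames(X))
      if (anyNA(idx)) stop("unknown unit column(s): ",
                           paste(u[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(u)
  })
}

# R^2 of the subset with columns `cols`, from second-moment quantities:
# Sxx (cols x cols covariance-scale matrix), sxy, vy. Rank-deficient subsets
# fall back to the minimum-norm (pseudoinverse) solution; R^2 stays the
# squared projection length and is well-defined.
subset_r2 <- function(Sxx, sxy, vy, cols) {
  if (length(cols) == 0L) return(0)
  A <- Sxx[cols, cols, drop = FALSE]
  b <- sxy[cols]
  beta <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
  max(0, sum(b * beta) / vy)
}

# shared engine: LMG from (Sxx, sxy, vy); used on sample cross-products by
# lmg() and on the analytic implied covariance by true_contributions()
lmg_from_moments <- function(Sxx, sxy, vy, units) {
  p <- length(units)
  if (p > 20L) stop("more than 20 regressor units (2^p enumeration bound)")
  nsub <- bitwShiftL(1L, p)
  r2 <- numeric(nsub)                       # index = bitmask + 1
  popcount <- integer(nsub)
  for (mask in seq_len(nsub - 1L)) {
    in_set <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    popcount[mask + 1L] <- length(in_set)
    r2[mask + 1L] <- subset_r2(Sxx, sxy, vy,
                               unlist(units[in_set], use.names = FALSE))
  }
  # Shapley weights by subset size t = |T| (unit u excluded)
  wt <- exp(lfactorial(0:(p - 1L)) + lfactorial(p - 1L - (0:(p - 1L))) -
              lfactorial(p))
  shares <- numeric(p)
  for (u in seq_len(p)) {
    bit <- bitwShiftL(1L, u - 1L)
    without <- which(bitwAnd(seq_len(nsub) - 1L, bit) == 0L)  # masks w/o u
    masks <- without - 1L
    inc <- pmax(r2[bitwOr(masks, bit) + 1L] - r2[masks + 1L], 0)
    shares[u] <- sum(wt[popcount[masks + 1L] + 1L] * inc)
  }
  stats::setNames(shares, names(units))
}

#' Ordinary least squares fit with R-squared
#'
#' Fits `y ~ 1 + X` by QR decomposition and returns coefficients and
#' `R^2 = 1 - RSS/TSS`. A rank-deficient design is an error (the calling
#' replicate is flagged).
#'
#' @param X numeric design matrix without intercept column.
#' @param y numeric response.
#' @return list with `intercept`, named `coefficients`, `r2`, `fitted`.
#' @export
fit_linear_model <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X) + 1L)
    stop("need more test rows than regression coefficients")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1L)
    stop("rank-deficient test design matrix")
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  list(intercept = unname(fit$coefficients[1L]),
       coefficients = stats::setNames(fit$coefficients[-1L], colnames(X)),
       r2 = 1 - rss / tss,
       fitted = fit$fitted.values)
}

#' LMG shares of R-squared over regressor units
#'
#' Production path: the Shapley subset-sum identity
#' `share(u) = sum_T |T|! (p-|T|-1)! / p! * (R2(T + u) - R2(T))`
#' over all subsets T of the other units, with subset R-squareds computed
#' from one set of precomputed cross-product matrices. Equivalent to
#' averaging sequential R-squareds over all p! unit orderings (the literal
#' form kept as test oracle in [lmg_bruteforce()]).
#'
#' @param X numeric design matrix without intercept.
#' @param y numeric response.
#' @param units list (ideally named) of column-name or column-index vectors;
#'   the units must partition the columns you want decomposed. At most 20
#'   units.
#' @return named numeric vector of shares; nonnegative, summing to the
#'   full-model R-squared.
#' @export
lmg <- function(X, y, units) {
  X <- as.matrix(X)
  units <- resolve_units(units, X)
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  lmg_from_moments(crossprod(Xc), drop(crossprod(Xc, yc)), sum(yc^2), units)
}

# all permutations of 1..p (p <= 7)
all_perms <- function(p) {
  if (p == 1L) return(list(1L))
  out <- list()
  for (perm in all_perms(p - 1L))
    for (pos in 0:(p - 1L))
      out[[length(out) + 1L]] <- append(perm, p, after = pos)
  out
}

#' Brute-force LMG by enumerating all unit orderings
#'
#' Literal definition: for every one of the p! orderings of the units,
#' compute each unit's sequential R-squared increment, then average. Test
#' oracle for [lmg()]; limited to 7 units.
#'
#' @inheritParams lmg
#' @return named numeric vector of shares.
#' @export
lmg_bruteforce <- function(X, y, units) {
  X <- as.matrix(X)
  units <- resolve_units(units, X)
  p <- length(units)
  if (p > 7L) stop("more than 7 units: p! enumeration refused")
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  Sxx <- crossprod(Xc)
  sxy <- drop(crossprod(Xc, yc))
  vy <- sum(yc^2)
  r2_cache <- new.env(parent = emptyenv())
  r2_of <- function(mask) {
    key <- as.character(mask)
    if (is.null(r2_cache[[key]])) {
      in_set <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      r2_cache[[key]] <- subset_r2(Sxx, sxy, vy,
                                   unlist(units[in_set], use.names = FALSE))
    }
    r2_cache[[key]]
  }
  shares <- numeric(p)
  perms <- all_perms(p)
  for (perm in perms) {
    mask <- 0L
    for (u in perm) {
      new_mask <- bitwOr(mask, bitwShiftL(1L, u - 1L))
      shares[u] <- shares[u] + max(r2_of(new_mask) - r2_of(mask), 0)
      mask <- new_mask
    }
  }
  stats::setNames(shares / length(perms), names(units))
}
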