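# Ridge regression with per-coefficient penalty factors.
#
# The objective is fixed and public:
#   (1/(2n)) * sum_i (y_i - g0 - x_i' g)^2 + lambda * sum_j pf_j * g_j^2
# with pf_j = 0 for unpenalized (single) predictors and pf_j = 1 for category
# members. On centered data the minimizer solves
#   (X'X/n + 2*lambda*diag(pf)) g = X'(y - ybar)/n ,   g0 = ybar - xbar' g.
# The whole lambda path is solved at once through the Schur complement of the
# unpenalized block and one eigendecomposition of the penalized block, so
# cross-validation over a 100-value grid costs one small eigen per fold.

solve_sym <- function(A, b) {
  tryCatch(solve(A, b),
           error = function(e)
             stop("singular system (collinear unpenalized block?): ",
                  conditionMessage(e), call. = FALSE))
}

# solve the centered normal equations (S + 2*lambda*diag(pf)) g = s for all
# lambdas at once; S = Xc'Xc/n, s = Xc'yc/n. Returns the p x L matrix.
ridge_solve_core <- function(S, s, penalty, lambdas) {
  p <- ncol(S)
  up <- which(penalty == 0)
  pe <- which(penalty > 0)
  L <- length(lambdas)
  G <- matrix(0, p, L)

  if (length(pe) == 0L) {
    G[] <- solve_sym(S, s)
  } else {
    if (length(up)) {
      Suu <- S[up, up, drop = FALSE]
      Suu_inv_su <- solve_sym(Suu, s[up])
      Suu_inv_Sup <- solve_sym(Suu, S[up, pe, drop = FALSE])
      M <- S[pe, pe, drop = FALSE] - S[pe, up, drop = FALSE] %*% Suu_inv_Sup
      r <- s[pe] - drop(S[pe, up, drop = FALSE] %*% Suu_inv_su)
    } else {
      M <- S[pe, pe, drop = FALSE]
      r <- s[pe]
    }
    M <- (M + t(M)) / 2
    eig <- eigen(M, symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    if (any(lambdas == 0) && min(ev) <= max(ev, 1e-300) * 1e-12)
      stop("ridge system is singular at lambda = 0")
    qtr <- drop(crossprod(eig$vectors, r))
    denom <- outer(ev, 2 * lambdas, `+`)
    Gp <- eig$vectors %*% (qtr / denom)
    G[pe, ] <- Gp
    if (length(up))
      G[up, ] <- Suu_inv_su - Suu_inv_Sup %*% Gp
  }
  G
}

# coefficients for all lambdas at once; returns list(intercept = L-vector,
# coefficients = p x L matrix)
ridge_solve_path <- function(X, y, penalty, lambdas) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  G <- ridge_solve_core(crossprod(Xc) / n, drop(crossprod(Xc, yc)) / n,
                        penalty, lambdas)
  list(intercept = ybar - drop(crossprod(G, xbar)), coefficients = G)
}

#' Bundle a penalized regression problem
#'
#' @param y numeric response (training outcome).
#' @param X numeric design matrix (no intercept column); columns are single
#'   predictors and category members.
#' @param penalty per-column penalty factors: exactly 0 for unpenalized
#'   single predictors, 1 for regularized category members.
#' @return object of class `ridge_problem`.
#' @export
ridge_problem <- function(y, X, penalty) {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), nrow(X) == length(y),
            length(penalty) == ncol(X), all(penalty %in% c(0, 1)))
  structure(list(y = as.numeric(y), X = X, penalty = as.numeric(penalty)),
            class = "ridge_problem")
}

#' Fit ridge regression with penalty factors at one lambda
#'
#' Minimizes `(1/(2n)) * RSS + lambda * sum_j pf_j * g_j^2` in closed form via
#' the normal equations on centered data (see package vignette). `lambda = 0`
#' with a full-rank design reproduces OLS; as `lambda` grows the penalized
#' block shrinks to zero while the unpenalized block tends to the OLS fit on
#' the single predictors alone.
#'
#' @param problem a [ridge_problem()].
#' @param lambda nonnegative penalty.
#' @return list with `intercept` and named `coefficients`.
#' @export
fit_ridge <- function(problem, lambda) {
  stopifnot(inherits(problem, "ridge_problem"), lambda >= 0)
  n_up <- sum(problem$penalty == 0)
  if (nrow(problem$X) <= n_up + 1L)
    stop("need more training rows than unpenalized coefficients")
  fit <- ridge_solve_path(problem$X, problem$y, problem$penalty, lambda)
  list(intercept = fit$intercept[1L],
       coefficients = stats::setNames(fit$coefficients[, 1L],
                                      colnames(problem$X)))
}

#' Descending lambda grid for cross-validation
#'
#' Anchored at `lambda_max = max_j |x_j'(y - ybar)| / n` over penalized
#' columns (a ridge-safe surrogate for the usual glmnet anchor, which is
#' infinite at alpha = 0), descending log-linearly to
#' `lambda_max * min_ratio`.
#'
#' @param problem a [ridge_problem()].
#' @param n_lambda grid length.
#' @param min_ratio ratio of smallest to largest lambda.
#' @return strictly decreasing positive numeric vector.
#' @export
lambda_grid <- function(problem, n_lambda = 100, min_ratio = 1e-4) {
  pe <- which(problem$penalty > 0)
  if (length(pe) == 0L) stop("no penalized predictors")
  Xp <- problem$X[, pe, drop = FALSE]
  if (all(apply(Xp, 2L, function(col) max(col) == min(col))))
    stop("all penalized predictors are constant")
  n <- nrow(Xp)
  yc <- problem$y - mean(problem$y)
  Xpc <- sweep(Xp, 2L, colMeans(Xp))
  lmax <- max(abs(drop(crossprod(Xpc, yc))) / n)
  lmax <- max(lmax, sqrt(.Machine$double.eps))
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Choose lambda by k-fold cross-validation
#'
#' Folds are assigned by a random permutation into `folds` near-equal parts;
#' the selected lambda minimizes the pooled out-of-fold squared error. Ties
#' resolve to the largest (most shrinking) lambda. Deterministic given
#' `seed`.
#'
#' @param problem a [ridge_problem()].
#' @param folds number of folds (default 10).
#' @param grid descending lambda grid, e.g. from [lambda_grid()].
#' @param seed integer seed for the fold assignment.
#' @return the selected lambda (scalar).
#' @export
cv_select_lambda <- function(problem, folds = 10, grid, seed) {
  n <- nrow(problem$X)
  stopifnot(folds >= 2, n >= folds)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (min(tabulate(fold_id, folds)) < 2L)
    stop("a fold has fewer than 2 observations")
  # fold-train moments come from the totals minus the held-out fold's
  # contribution, so each fold only pays one small crossprod
  X <- problem$X
  y <- problem$y
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  cs <- colSums(X)
  ys <- sum(y)
  sse <- numeric(length(grid))
  for (f in seq_len(folds)) {
    out <- fold_id == f
    Xo <- X[out, , drop = FALSE]
    yo <- y[out]
    n_tr <- n - nrow(Xo)
    xbar <- (cs - colSums(Xo)) / n_tr
    ybar <- (ys - sum(yo)) / n_tr
    S <- (XtX - crossprod(Xo)) / n_tr - tcrossprod(xbar)
    s <- (Xty - drop(crossprod(Xo, yo))) / n_tr - xbar * ybar
    G <- ridge_solve_core(S, s, problem$penalty, grid)
    pred <- Xo %*% G
    pred <- sweep(pred, 2L, ybar - drop(crossprod(G, xbar)), `+`)
    sse <- sse + colSums((yo - pred)^2)
  }
  grid[which.min(sse)]
}

#' Normalize averaged ridge coefficients into risk-score weights
#'
#' Signed-sum normalization: if any averaged coefficient is nonzero,
#' `w_j = g_j / sum_l g_l`, which guarantees the weights sum to one; if all
#' coefficients are (numerically) zero the uniform fallback `1/m` applies.
#' When the signed sum nearly cancels (`|sum g| < 1e-8 * sum |g|`) the
#' normalization is unstable; the category falls back to uniform weights and
#' the event is flagged via attribute `"fallback" = "cancellation"`.
#'
#' Note that the signed-sum denominator guarantees sum-to-one but not
#' `|w| <= 1` when coefficients have mixed signs (e.g. `g = (3, -1)` gives
#' `w = (1.5, -0.5)`).
#'
#' @param gamma averaged coefficient vector of one category's members.
#' @param zero_tol absolute threshold below which a coefficient counts as
#'   zero (default 1e-12).
#' @param cancel_tol relative near-cancellation guard (default 1e-8).
#' @return numeric weight vector summing to one, with attribute `"fallback"`
#'   set to `"all_zero"` or `"cancellation"` when the uniform branch fired.
#' @export
normalize_weights <- function(gamma, zero_tol = 1e-12, cancel_tol = 1e-8) {
  m <- length(gamma)
  stopifnot(m >= 1L)
  if (all(abs(gamma) <= zero_tol)) {
    w <- rep(1 / m, m)
    attr(w, "fallback") <- "all_zero"
  } else if (abs(sum(gamma)) < cancel_tol * sum(abs(gamma))) {
    w <- rep(1 / m, m)
    attr(w, "fallback") <- "cancellation"
  } else {
    w <- gamma / sum(gamma)
  }
  names(w) <- names(gamma)
  w
}

#' Learn normalized risk-score weights on a training sample
#'
#' Builds the penalized regression problem (single predictors unpenalized,
#' all category members penalized), selects lambda by cross-validation, fits,
#' and repeats `cv_repeats` times with fresh fold randomizations; the
#' coefficient estimates are averaged elementwise across repeats and each
#' category's averaged coefficients are passed through [normalize_weights()].
#'
#' Columns that are constant in the training sample (possible for rare
#' binary members under resampling) are excluded from the fit, their
#' coefficients forced to 0 before normalization, and flagged.
#'
#' @param train standardized training table.
#' @param design a validated [study_design()].
#' @param config an [analysis_config()].
#' @param seed integer seed; each repeat draws folds from its own derived
#'   stream.
#' @return list with `weights` (named list of per-category weight vectors),
#'   `gamma` (averaged coefficients), `lambdas` (selected lambda per repeat)
#'   and `flags` (character vector of logged events).
#' @export
learn_category_weights <- function(train, design, config, seed = config$seed) {
  singles <- design$singles
  members <- design_members(design)
  X <- as.matrix(train[, c(singles, members), drop = FALSE])
  y <- train[[design$outcome]]
  penalty <- c(rep(0, length(singles)), rep(1, length(members)))
  flags <- character()

  const <- apply(X, 2L, function(col) max(col) == min(col))
  if (any(const))
    flags <- c(flags, paste0("degenerate_column:", colnames(X)[const]))
  keep <- !const

  gbar <- stats::setNames(numeric(ncol(X)), colnames(X))
  lambdas <- rep(NA_real_, config$cv_repeats)
  if (any(keep & penalty > 0)) {
    problem <- ridge_problem(y, X[, keep, drop = FALSE], penalty[keep])
    grid <- lambda_grid(problem, config$n_lambda, config$lambda_min_ratio)
    gsum <- numeric(sum(keep))
    for (r in seq_len(config$cv_repeats)) {
      lam <- cv_select_lambda(problem, config$cv_folds, grid,
                              seed = derive_seed(seed, 303L, r))
      lambdas[r] <- lam
      gsum <- gsum + fit_ridge(problem, lam)$coefficients
    }
    gbar[keep] <- gsum / config$cv_repeats
  }

  weights <- list()
  for (k in names(design$categories)) {
    w <- normalize_weights(gbar[design$categories[[k]]])
    if (!is.null(attr(w, "fallback")))
      flags <- c(flags, paste0("weight_fallback:", k, ":", attr(w, "fallback")))
    weights[[k]] <- w
  }
  list(weights = weights, gamma = gbar, lambdas = lambdas, flags = flags)
}
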