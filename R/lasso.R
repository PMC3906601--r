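## L1-penalised least squares. The objective follows the association model
## verbatim:  f(beta) = sum_i (y_i - x_i' beta)^2 + lambda * sum_j |beta_j|
## (no 1/2N factor, no intercept: y is centred per trait and features are
## z-scored). Hence the whole path is zero for lambda >= 2 * max_j |x_j' y|.

#' Largest useful lasso penalty
#'
#' Smallest `lambda` for which the all-zero vector solves the penalised
#' problem: `2 * max_j |x_j' y|`.
#'
#' @param X numeric design matrix (samples x features).
#' @param y numeric response vector.
#' @return a nonnegative scalar.
#' @export
lambda_max <- function(X, y) {
  2 * max(abs(crossprod(X, y)))
}

#' Geometric penalty grid
#'
#' 100 points (by default) descending geometrically from [lambda_max()] to
#' `lambda_max * min_ratio`.
#'
#' @param X,y design and response.
#' @param n_lambda grid length.
#' @param min_ratio ratio of the smallest to the largest penalty.
#' @return a decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, min_ratio = 1e-3) {
  lmax <- lambda_max(X, y)
  if (lmax <= 0) stop("response is orthogonal to every feature (lambda_max = 0)")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit the lasso at a fixed penalty
#'
#' Cyclic coordinate descent on the objective
#' `sum((y - X beta)^2) + lambda * sum(|beta|)`, without intercept.
#' Deterministic for fixed inputs (fixed cyclic coordinate order). The
#' returned solution satisfies the KKT conditions: for active coordinates
#' `|2 x_j'(y - X beta)| = lambda`, for inactive ones
#' `|2 x_j'(y - X beta)| <= lambda`, up to the convergence tolerance.
#'
#' @param X numeric matrix (samples x features), typically with z-scored
#'   columns.
#' @param y numeric response, typically centered.
#' @param lambda nonnegative penalty.
#' @param beta_init optional warm start (defaults to zero).
#' @param tol convergence tolerance: stop when the largest coefficient
#'   change in a full sweep is below `tol * max(1, max(|beta|))`.
#' @param max_sweeps sweep cap; if reached the best iterate is returned with
#'   `converged = FALSE`.
#' @return an object of class `lasso_fit` with elements `coefficients`
#'   (named), `lambda`, `objective`, `n_iter`, `converged`.
#' @export
lasso_fit <- function(X, y, lambda, beta_init = NULL, tol = 1e-11,
                      max_sweeps = 10000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), is.numeric(lambda), length(lambda) == 1,
            lambda >= 0, all(is.finite(X)), all(is.finite(y)))
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  stopifnot(length(beta_init) == ncol(X))
  res <- .cd_lasso(X, y, lambda, as.numeric(beta_init), tol,
                   as.integer(max_sweeps))
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, lambda = lambda,
                 objective = res$objective, n_iter = res$n_iter,
                 converged = res$converged),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda=%.4g  %d/%d nonzero  objective=%.6g  %s\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients),
              x$objective,
              if (x$converged) sprintf("converged in %d sweeps", x$n_iter)
              else "NOT converged"))
  invisible(x)
}

#' @export
coef.lasso_fit <- function(object, ...) object$coefficients

#' Warm-started lasso solution path
#'
#' @inheritParams lasso_fit
#' @param lambdas decreasing vector of penalties.
#' @param saturate_frac if positive, stop descending the path once the
#'   training RSS falls below `saturate_frac * sum(y^2)` (the fit has
#'   saturated; remaining grid points reuse the current solution). Used by
#'   the cross-validation driver; 0 disables.
#' @return list with `beta` (features x lambdas matrix), `lambdas`,
#'   `n_iter`, `converged`.
#' @export
lasso_path <- function(X, y, lambdas, tol = 1e-9, max_sweeps = 10000L,
                       saturate_frac = 0) {
  X <- as.matrix(X)
  stopifnot(length(lambdas) >= 1, all(lambdas >= 0),
            !is.unsorted(rev(lambdas)))
  res <- .cd_lasso_path(X, as.numeric(y), as.numeric(lambdas), tol,
                        as.integer(max_sweeps),
                        saturate_frac * sum(as.numeric(y)^2))
  rownames(res$beta) <- colnames(X)
  list(beta = res$beta, lambdas = lambdas, n_iter = res$n_iter,
       converged = res$converged)
}

#' KKT residuals of a lasso solution
#'
#' Returns, per coordinate, the violation of the stationarity conditions of
#' the penalised objective, with `g_j = 2 x_j'(y - X beta)`: active
#' coordinates must satisfy `g_j = lambda * sign(beta_j)` (violation
#' `|g_j - lambda * sign(beta_j)|`), inactive ones `|g_j| <= lambda`
#' (violation `max(0, |g_j| - lambda)`).
#'
#' @param fit a `lasso_fit`.
#' @param X,y the data the fit was computed on.
#' @return numeric vector of nonnegative violations, one per feature.
#' @export
lasso_kkt <- function(fit, X, y) {
  beta <- fit$coefficients
  g <- 2 * as.numeric(crossprod(X, y - X %*% beta))
  active <- beta != 0
  viol <- numeric(length(beta))
  viol[active] <- abs(g[active] - fit$lambda * sign(beta[active]))
  viol[!active] <- pmax(0, abs(g[!active]) - fit$lambda)
  viol
}

#' Cross-validated penalty selection
#'
#' K-fold cross-validation over a descending penalty grid; the chosen
#' penalty minimises the mean held-out squared error (ties resolved toward
#' the larger, sparser penalty). Fold assignment is drawn deterministically
#' from `seed`.
#'
#' @inheritParams lasso_fit
#' @inheritParams lasso_path
#' @param n_folds number of folds (>= 2).
#' @param grid descending positive penalty grid; defaults to
#'   [lambda_grid()].
#' @param seed integer seed for the fold assignment.
#' @param n_lambda,min_ratio passed to [lambda_grid()] when `grid` is NULL.
#' @details The per-fold paths use a moderate tolerance, a per-penalty
#'   sweep cap and a saturation early-stop: held-out prediction error is insensitive to the last
#'   digits of the training coefficients, and the saturated small-penalty
#'   tail (reachable when features outnumber training samples) never
#'   minimises the held-out error. The final fit at the chosen penalty
#'   should use a strict tolerance (see [lasso_fit()]).
#' @return list with `lambda` (chosen), `grid`, `cv_error` (mean held-out
#'   MSE per grid point), `n_folds`, `seed`.
#' @export
select_lambda_cv <- function(X, y, n_folds = 10, grid = NULL, seed = 1,
                             n_lambda = 100, min_ratio = 1e-3, tol = 1e-5,
                             max_sweeps = 50L, saturate_frac = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n_folds >= 2, n >= n_folds)
  if (var(y) == 0) stop("degenerate response: zero variance")
  if (!is.null(grid) && length(grid) == 0) stop("empty penalty grid")
  if (is.null(grid))
    grid <- lambda_grid(X, y, n_lambda = n_lambda, min_ratio = min_ratio)
  stopifnot(all(grid > 0), !is.unsorted(rev(grid)))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  folds <- sample(rep_len(seq_len(n_folds), n))
  sse <- numeric(length(grid))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    path <- lasso_path(X[tr, , drop = FALSE], y[tr], grid, tol = tol,
                       max_sweeps = max_sweeps,
                       saturate_frac = saturate_frac)
    pred <- X[!tr, , drop = FALSE] %*% path$beta
    sse <- sse + colSums((y[!tr] - pred)^2)
  }
  cv_error <- sse / n
  best <- which(cv_error <= min(cv_error))[1]  # ties -> larger lambda
  list(lambda = grid[best], grid = grid, cv_error = cv_error,
       n_folds = n_folds, seed = seed)
}

# Seed hygiene: run a block under a known seed and restore the caller's RNG
# state afterwards, so per-gene fits are independent of execution order.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
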