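## Two-stage Screen-and-Clean selection: lasso screening on one half of the
## samples (penalty chosen by cross-validation inside that half), then
## ordinary least squares with t-tests on the other, disjoint half. Because
## screening and testing use disjoint data, the clean-stage p-values of null
## features are uniform, and the flat 0.05 threshold controls the per-tested-
## feature false selection rate at its nominal level.

#' Screen-and-Clean feature selection with p-values
#'
#' Splits the samples into a screen half and a clean half, runs a
#' cross-validated lasso on the screen half to obtain a candidate set (the
#' nonzero coefficients at the CV-chosen penalty), then regresses the clean
#' half's response on the candidate columns by OLS and keeps the features
#' whose two-sided t-test p-value is at most `alpha`.
#'
#' The clean-stage OLS includes an intercept: the response is centred
#' globally, not per half, so the clean half has a nonzero sample mean that
#' would otherwise bias the t-tests. Reported coefficients are the
#' clean-stage OLS slope estimates; their magnitudes are the association
#' strengths used downstream.
#'
#' If the screen set is too large for the clean regression
#' (`|S| >= n_clean - 1`), it is truncated to the largest-magnitude
#' screen-stage coefficients that keep the regression overdetermined, and
#' the result records the truncation. Exactly collinear candidate columns
#' are dropped from the clean stage and recorded.
#'
#' @param X numeric matrix (samples x features) with standardized columns.
#' @param y centered numeric response.
#' @param alpha significance threshold for the clean-stage p-values
#'   (default 0.05).
#' @param split_fraction fraction of samples assigned to the screen half
#'   (default 0.5).
#' @param seed integer seed controlling the split and the CV folds.
#' @param n_folds CV folds for the penalty search inside the screen half.
#' @param n_lambda,min_ratio penalty-grid shape (see [lambda_grid()]).
#' @param tol,max_sweeps coordinate-descent controls for the screen-stage
#'   fit at the chosen penalty; the CV paths use the moderate defaults of
#'   [select_lambda_cv()].
#' @return an object of class `clean_result`: `selected` (indices into the
#'   columns of `X`), `coefficients` and `p_values` (named, one per
#'   clean-tested feature), `screen_set`, `lambda`, `truncated`,
#'   `dropped_collinear`, `split` (screen/clean index vectors), `alpha`,
#'   `seed`.
#' @export
screen_and_clean <- function(X, y, alpha = 0.05, split_fraction = 0.5,
                             seed = 1, n_folds = 10, n_lambda = 100,
                             min_ratio = 1e-3, tol = 1e-9,
                             max_sweeps = 10000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, alpha > 0, alpha < 1,
            split_fraction > 0, split_fraction < 1)
  if (n < 20)
    stop("need at least 20 samples so both halves support fitting")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  perm <- sample.int(n)
  n_screen <- floor(split_fraction * n)
  screen_idx <- sort(perm[seq_len(n_screen)])
  clean_idx <- sort(perm[-seq_len(n_screen)])
  cv_seed <- sample.int(2147483646L, 1)

  Xs <- X[screen_idx, , drop = FALSE]
  ys <- y[screen_idx]
  cv <- select_lambda_cv(Xs, ys, n_folds = n_folds, seed = cv_seed,
                         n_lambda = n_lambda, min_ratio = min_ratio)
  sfit <- lasso_fit(Xs, ys, cv$lambda, tol = tol, max_sweeps = max_sweeps)
  screen_set <- unname(which(sfit$coefficients != 0))

  empty <- function(truncated = FALSE) {
    structure(list(selected = integer(0),
                   coefficients = setNames(numeric(0), character(0)),
                   p_values = setNames(numeric(0), character(0)),
                   screen_set = screen_set, lambda = cv$lambda,
                   truncated = truncated, dropped_collinear = character(0),
                   split = list(screen = screen_idx, clean = clean_idx),
                   alpha = alpha, seed = seed),
              class = "clean_result")
  }
  if (length(screen_set) == 0) return(empty())

  n_clean <- length(clean_idx)
  truncated <- FALSE
  S <- screen_set
  if (length(S) >= n_clean - 1) {
    truncated <- TRUE
    keep_n <- max(1L, n_clean - 2L)
    ord <- order(-abs(sfit$coefficients[S]), S)
    S <- sort(S[ord[seq_len(min(keep_n, length(S)))]])
  }

  Xc <- X[clean_idx, S, drop = FALSE]
  yc <- y[clean_idx]
  fit <- lm(yc ~ Xc)
  sm <- summary(fit)$coefficients
  cf <- coef(fit)[-1]            # drop intercept
  dropped <- S[is.na(cf)]
  kept <- S[!is.na(cf)]
  if (length(kept) == 0) {
    out <- empty(truncated)
    out$dropped_collinear <- colname_or_index(X, dropped)
    return(out)
  }
  # summary() drops NA-coefficient rows, so its slope rows align with `kept`
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  est <- sm[, "Estimate"]
  pv <- sm[, "Pr(>|t|)"]
  nm <- colname_or_index(X, kept)
  names(est) <- nm
  names(pv) <- nm
  sel <- kept[pv <= alpha]
  structure(list(selected = sel, coefficients = est, p_values = pv,
                 screen_set = screen_set, lambda = cv$lambda,
                 truncated = truncated,
                 dropped_collinear = colname_or_index(X, dropped),
                 split = list(screen = screen_idx, clean = clean_idx),
                 alpha = alpha, seed = seed),
            class = "clean_result")
}

colname_or_index <- function(X, idx) {
  if (is.null(colnames(X))) as.character(idx) else colnames(X)[idx]
}

#' @export
print.clean_result <- function(x, ...) {
  cat(sprintf(
    "<clean_result> screened %d, selected %d at alpha=%.3g (lambda=%.4g)%s\n",
    length(x$screen_set), length(x$selected), x$alpha, x$lambda,
    if (x$truncated) " [screen set truncated]" else ""))
  invisible(x)
}
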