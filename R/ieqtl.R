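## Per-gene model fitting. In integrative mode the blocks are concatenated
## column-wise in canonical type order (CNA, methylation, miRNA) and a
## single penalty is applied to the stacked coefficient vector, which is
## exactly a plain lasso on the stacked design; in single mode the same
## Screen-and-Clean machinery runs on one block at a time. Every gene is
## fitted under its own derived seed, so results do not depend on execution
## order or on which subset of genes is requested.

#' Control parameters for [ieqtl()]
#'
#' @param alpha clean-stage significance threshold (default 0.05).
#' @param split_fraction screen/clean split (default 0.5).
#' @param cv_folds folds for the penalty cross-validation (default 10).
#' @param n_lambda,lambda_min_ratio penalty-grid shape.
#' @param accuracy compute cross-validated prediction accuracy per gene?
#'   (5-fold selection + refit per fold; substantially more expensive).
#' @param accuracy_folds folds for the accuracy cross-validation (default 5).
#' @param rho_accuracy association-strength threshold applied before the
#'   accuracy refit (default 0.1): selected features with
#'   `|beta| < rho_accuracy` are discarded and the model refitted on the
#'   survivors.
#' @param seed global integer seed; per-gene seeds are derived from it and
#'   the gene's index so runs are reproducible and genes independent.
#' @param tol,max_sweeps coordinate-descent controls.
#' @return a list of class `ieqtl_control`.
#' @export
ieqtl_control <- function(alpha = 0.05, split_fraction = 0.5, cv_folds = 10,
                          n_lambda = 100, lambda_min_ratio = 1e-3,
                          accuracy = FALSE, accuracy_folds = 5,
                          rho_accuracy = 0.1, seed = 1, tol = 1e-9,
                          max_sweeps = 10000L) {
  stopifnot(alpha > 0, alpha < 1, split_fraction > 0, split_fraction < 1,
            cv_folds >= 2, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1, accuracy_folds >= 2, rho_accuracy >= 0,
            seed == as.integer(seed))
  structure(list(alpha = alpha, split_fraction = split_fraction,
                 cv_folds = cv_folds, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 accuracy = isTRUE(accuracy),
                 accuracy_folds = accuracy_folds,
                 rho_accuracy = rho_accuracy, seed = as.integer(seed),
                 tol = tol, max_sweeps = as.integer(max_sweeps)),
            class = "ieqtl_control")
}

# column-bind the requested blocks in canonical type order; column names are
# "type|feature" so identifiers stay unique across types
stack_design <- function(dataset, types) {
  types <- intersect(OMICS_TYPES, types)
  missing <- setdiff(types, names(dataset$blocks))
  if (length(missing))
    stop("dataset has no block of type: ", paste(missing, collapse = ", "))
  mats <- lapply(types, function(ty) {
    b <- dataset$blocks[[ty]]
    if (ncol(b$values) == 0) stop("empty ", ty, " block (0 features)")
    m <- b$values
    colnames(m) <- paste(ty, colnames(m), sep = "|")
    m
  })
  X <- do.call(cbind, mats)
  map <- data.frame(
    col = colnames(X),
    feature_type = rep(types, vapply(mats, ncol, 1L)),
    feature_id = sub("^[^|]*\\|", "", colnames(X)),
    stringsAsFactors = FALSE)
  list(X = X, map = map)
}

#' Fit the integrative (or single-type) sparse eQTL model
#'
#' For every requested gene, regresses the centred expression trait on the
#' z-scored genomic features with a cross-validated lasso followed by
#' Screen-and-Clean filtering, and records the selected features, their
#' clean-stage coefficients (association strengths) and p-values.
#'
#' @param dataset a normalized `multiomics_dataset` (see
#'   [align_samples()] and [normalize_dataset()]).
#' @param mode `"integrative"` fits all feature types jointly under one
#'   penalty on the concatenated design; `"CNA"`, `"methylation"` or
#'   `"miRNA"` fits that single block alone.
#' @param genes character vector of gene ids to fit (default: every gene
#'   with positive expression variance). Zero-variance genes are skipped
#'   and recorded.
#' @param control an [ieqtl_control()].
#' @return an object of class `ieqtl` with per-gene fit records, run
#'   metadata, and methods `print`, `summary`, `coef`, `predict`, `plot`.
#' @export
ieqtl <- function(dataset, mode = c("integrative", OMICS_TYPES),
                  genes = NULL, control = ieqtl_control()) {
  stopifnot(inherits(dataset, "multiomics_dataset"),
            inherits(control, "ieqtl_control"))
  mode <- match.arg(mode)
  if (!all(vapply(dataset$blocks, function(b) b$normalized, TRUE)))
    stop("all blocks must be z-score normalized before fitting; ",
         "see normalize_dataset()")
  expr <- dataset$expression
  if (!identical(expr$sample_ids, dataset$sample_ids) ||
      !all(vapply(dataset$blocks,
                  function(b) identical(block_samples(b),
                                        dataset$sample_ids), TRUE)))
    stop("sample ordering inconsistent; rebuild with align_samples()")
  types <- if (mode == "integrative") names(dataset$blocks) else mode
  design <- stack_design(dataset, types)
  mode_label <- if (mode == "integrative") "integrative"
                else paste0("single:", mode)

  all_genes <- expr$gene_ids
  if (is.null(genes)) genes <- setdiff(all_genes, expr$zero_variance)
  unknown <- setdiff(genes, all_genes)
  if (length(unknown))
    stop("gene(s) not in expression matrix: ",
         paste(head(unknown, 5), collapse = ", "))

  old <- local_seed(control$seed)
  gene_seeds <- sample.int(2147483646L, length(all_genes))
  restore_seed(old)
  names(gene_seeds) <- all_genes

  fits <- list()
  skipped <- character(0)
  failures <- list()
  for (g in genes) {
    if (expr$sigma[g] == 0) {
      skipped <- c(skipped, g)
      next
    }
    rec <- tryCatch(
      fit_one_gene(design, expr, g, mode_label, control, gene_seeds[[g]]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[g]] <- conditionMessage(rec)
    } else {
      fits[[g]] <- rec
    }
  }
  structure(list(
    fits = fits, mode = mode_label, control = control,
    gene_stats = data.frame(gene_id = all_genes, mu = unname(expr$mu),
                            sigma = unname(expr$sigma),
                            stringsAsFactors = FALSE),
    feature_map = design$map, N = dataset$N,
    types = types, skipped = skipped, failures = failures,
    sample_ids = dataset$sample_ids, call = match.call()),
    class = "ieqtl")
}

fit_one_gene <- function(design, expr, gene_id, mode_label, control, seed) {
  y <- as.numeric(expr$values[gene_id, ])
  yc <- y - mean(y)
  old <- local_seed(seed)
  sc_seed <- sample.int(2147483646L, 1)
  acc_seed <- sample.int(2147483646L, 1)
  restore_seed(old)
  res <- screen_and_clean(design$X, yc, alpha = control$alpha,
                          split_fraction = control$split_fraction,
                          seed = sc_seed, n_folds = control$cv_folds,
                          n_lambda = control$n_lambda,
                          min_ratio = control$lambda_min_ratio,
                          tol = control$tol,
                          max_sweeps = control$max_sweeps)
  sel_cols <- colnames(design$X)[res$selected]
  m <- design$map[match(sel_cols, design$map$col), , drop = FALSE]
  selected <- data.frame(
    feature_id = m$feature_id, feature_type = m$feature_type,
    beta = unname(res$coefficients[sel_cols]),
    p_value = unname(res$p_values[sel_cols]),
    stringsAsFactors = FALSE)
  rec <- list(gene_id = gene_id, mode = mode_label, selected = selected,
              screen_size = length(res$screen_set), lambda = res$lambda,
              truncated = res$truncated, seed = seed,
              accuracy = NA_real_, accuracy_insample = NA_real_,
              accuracy_flag = NA_character_)
  if (control$accuracy) {
    acc <- cv_prediction_accuracy(design, y, control, acc_seed)
    rec$accuracy <- acc$cv
    rec$accuracy_flag <- acc$flag
    rec$accuracy_insample <- insample_accuracy(design, y, selected, control)
  }
  rec
}

#' Pearson accuracy between predicted and observed traits
#'
#' The prediction-accuracy measure: the correlation across samples between
#' observed and predicted expression. Returns 0 with attribute
#' `flag = "undefined"` when either vector is constant.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return a scalar in `[-1, 1]`.
#' @export
accuracy_cor <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (sd(predicted) == 0 || sd(observed) == 0)
    return(structure(0, flag = "undefined"))
  cor(predicted, observed)
}

# k-fold cross-validated accuracy: selection and estimation are re-run on
# the training folds alone (features re-standardized and the trait
# re-centred within the training set), held-out predictions are pooled and
# correlated with the observed trait.
cv_prediction_accuracy <- function(design, y, control, seed) {
  n <- length(y)
  k <- control$accuracy_folds
  old <- local_seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  fold_seeds <- sample.int(2147483646L, k)
  restore_seed(old)
  pred <- numeric(n)
  any_model <- FALSE
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- design$X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    s <- sqrt(colSums(sweep(Xtr, 2, mu, "-")^2) / sum(tr))
    ok <- s > 0
    Xtr <- sweep(sweep(Xtr[, ok, drop = FALSE], 2, mu[ok], "-"), 2, s[ok],
                 "/")
    ytr <- y[tr]
    sc <- screen_and_clean(Xtr, ytr - mean(ytr), alpha = control$alpha,
                           split_fraction = control$split_fraction,
                           seed = fold_seeds[f], n_folds = control$cv_folds,
                           n_lambda = control$n_lambda,
                           min_ratio = control$lambda_min_ratio,
                           tol = control$tol,
                           max_sweeps = control$max_sweeps)
    surv <- sc$selected[abs(sc$coefficients[colnames(Xtr)[sc$selected]]) >=
                          control$rho_accuracy]
    Xte <- design$X[!tr, , drop = FALSE]
    if (length(surv) == 0) {
      pred[!tr] <- mean(ytr)
      next
    }
    any_model <- TRUE
    refit <- lm(ytr ~ Xtr[, surv, drop = FALSE])
    cols <- colnames(Xtr)[surv]
    Xte_s <- sweep(sweep(Xte[, cols, drop = FALSE], 2, mu[cols], "-"), 2,
                   s[cols], "/")
    b <- coef(refit)
    pred[!tr] <- b[1] + as.numeric(Xte_s %*% b[-1])
  }
  if (!any_model)
    return(list(cv = 0, flag = "no_model"))
  a <- accuracy_cor(pred, y)
  list(cv = as.numeric(a),
       flag = if (!is.null(attr(a, "flag"))) attr(a, "flag")
              else NA_character_)
}

insample_accuracy <- function(design, y, selected, control) {
  surv <- selected[abs(selected$beta) >= control$rho_accuracy, ,
                   drop = FALSE]
  if (nrow(surv) == 0) return(0)
  cols <- paste(surv$feature_type, surv$feature_id, sep = "|")
  refit <- lm(y ~ design$X[, cols, drop = FALSE])
  as.numeric(accuracy_cor(fitted(refit), y))
}

#' Cross-validated prediction accuracy for one gene
#'
#' Recomputes the headline accuracy measure for a single gene and mode:
#' within each fold, Screen-and-Clean selection and an OLS refit (after
#' discarding associations weaker than `control$rho_accuracy`) are re-run
#' on the training folds, held-out predictions are pooled, and the pooled
#' predictions are correlated with the observed trait.
#'
#' @inheritParams ieqtl
#' @param gene_id a single gene id present in the dataset.
#' @return list with `cv` (the cross-validated Pearson accuracy),
#'   `insample` (the optimistically biased in-sample counterpart) and
#'   `flag` (`"no_model"`/`"undefined"`/`NA`).
#' @export
prediction_accuracy <- function(dataset, gene_id,
                                mode = c("integrative", OMICS_TYPES),
                                control = ieqtl_control()) {
  mode <- match.arg(mode)
  fit <- ieqtl(dataset, mode = mode, genes = gene_id,
               control = within_control(control, accuracy = TRUE))
  rec <- fit$fits[[gene_id]]
  if (is.null(rec)) stop("fit failed for gene ", gene_id)
  list(cv = rec$accuracy, insample = rec$accuracy_insample,
       flag = rec$accuracy_flag)
}

within_control <- function(control, ...) {
  mods <- list(...)
  control[names(mods)] <- mods
  control
}

#' @export
print.ieqtl <- function(x, ...) {
  n_sel <- vapply(x$fits, function(f) nrow(f$selected), 1L)
  cat(sprintf("<ieqtl> mode=%s  %d genes fitted (N=%d samples)\n",
              x$mode, length(x$fits), x$N))
  cat(sprintf("  selected features per gene: median %g (range %g-%g)\n",
              if (length(n_sel)) median(n_sel) else NA,
              if (length(n_sel)) min(n_sel) else NA,
              if (length(n_sel)) max(n_sel) else NA))
  if (length(x$skipped))
    cat("  skipped (zero variance):", length(x$skipped), "\n")
  if (length(x$failures))
    cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' @export
summary.ieqtl <- function(object, ...) {
  fits <- object$fits
  tab <- data.frame(
    gene_id = vapply(fits, `[[`, "", "gene_id"),
    n_selected = vapply(fits, function(f) nrow(f$selected), 1L),
    lambda = vapply(fits, `[[`, 1, "lambda"),
    accuracy = vapply(fits, `[[`, 1, "accuracy"),
    accuracy_insample = vapply(fits, `[[`, 1, "accuracy_insample"),
    row.names = NULL, stringsAsFactors = FALSE)
  by_type <- table(factor(
    unlist(lapply(fits, function(f) f$selected$feature_type)),
    levels = OMICS_TYPES))
  structure(list(mode = object$mode, genes = tab, edges_by_type = by_type,
                 skipped = object$skipped, failures = object$failures),
            class = "summary.ieqtl")
}

#' @export
print.summary.ieqtl <- function(x, ...) {
  cat(sprintf("Integrative eQTL fit summary (mode=%s)\n", x$mode))
  cat(sprintf("  genes fitted: %d;  skipped: %d;  failed: %d\n",
              nrow(x$genes), length(x$skipped), length(x$failures)))
  cat("  selected associations by feature type:\n")
  print(x$edges_by_type)
  if (any(!is.na(x$genes$accuracy)))
    cat(sprintf("  mean CV prediction accuracy: %.3f\n",
                mean(x$genes$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Long coefficient table of a fit
#'
#' @param object an `ieqtl` fit.
#' @param ... unused.
#' @return data frame with one row per selected (gene, feature)
#'   association: `gene_id`, `feature_id`, `feature_type`, `beta`,
#'   `p_value`, `lambda`, `accuracy`.
#' @export
coef.ieqtl <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    if (nrow(f$selected) == 0) return(NULL)
    data.frame(gene_id = f$gene_id, f$selected, lambda = f$lambda,
               accuracy = f$accuracy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), feature_id = character(0),
                      feature_type = character(0), beta = numeric(0),
                      p_value = numeric(0), lambda = numeric(0),
                      accuracy = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Predicted expression from the fitted associations
#'
#' For each fitted gene, refits OLS of the observed trait on the selected
#' features (all samples) and returns the fitted values — the in-sample
#' predictions whose correlation with the observed trait is the in-sample
#' accuracy. Genes with no selected features predict their mean.
#'
#' @param object an `ieqtl` fit.
#' @param dataset the normalized `multiomics_dataset` the model was fitted
#'   on.
#' @param genes optional subset of fitted gene ids.
#' @param ... unused.
#' @return matrix of predictions, genes x samples.
#' @export
predict.ieqtl <- function(object, dataset, genes = NULL, ...) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  design <- stack_design(dataset, object$types)
  if (is.null(genes)) genes <- names(object$fits)
  out <- matrix(NA_real_, length(genes), dataset$N,
                dimnames = list(genes, dataset$sample_ids))
  for (g in genes) {
    f <- object$fits[[g]]
    if (is.null(f)) stop("gene not fitted: ", g)
    y <- as.numeric(dataset$expression$values[g, ])
    if (nrow(f$selected) == 0) {
      out[g, ] <- mean(y)
      next
    }
    cols <- paste(f$selected$feature_type, f$selected$feature_id, sep = "|")
    refit <- lm(y ~ design$X[, cols, drop = FALSE])
    out[g, ] <- fitted(refit)
  }
  out
}

#' Plot per-gene selection and accuracy of a fit
#'
#' Left panel: histogram of selected-set sizes. Right panel (when
#' accuracies were computed): cross-validated accuracy against the number
#' of selected features.
#'
#' @param x an `ieqtl` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.ieqtl <- function(x, ...) {
  n_sel <- vapply(x$fits, function(f) nrow(f$selected), 1L)
  acc <- vapply(x$fits, `[[`, 1, "accuracy")
  has_acc <- any(!is.na(acc))
  if (has_acc) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::hist(n_sel, main = paste("Selected features per gene,", x$mode),
                 xlab = "selected features", ...)
  if (has_acc)
    graphics::plot(n_sel, acc, xlab = "selected features",
                   ylab = "CV prediction accuracy", main = x$mode)
  invisible(x)
}
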