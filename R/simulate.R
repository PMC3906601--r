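## Synthetic multi-omics generator with known sparse ground truth. The
## generative model mirrors the association model read forwards: each
## driven trait is a sparse linear combination of z-scored features plus
## Gaussian noise. Marginals per type: CNA features are categorical calls
## in {-2,...,2} obtained by thresholding a latent Gaussian; methylation
## features are logit-normal beta-values in (0,1); miRNA features are
## Gaussian signals. Cross-type correlation — the mechanism that makes
## single-type analyses over-count synergistic genes — is induced by
## sharing latent Gaussian factors between designated feature pairs before
## the marginal transforms, which preserves each type's marginal family.

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults emulate, at desk scale, a tumor multi-omics study: few CNA
#' cytobands, many methylation features, an intermediate number of miRNAs
#' (preserving the CNA << miRNA << methylation proportions), standardized
#' effect sizes of moderate magnitude, unit trait noise and strong
#' cross-type feature correlation.
#'
#' @param N samples (default 200).
#' @param J named feature counts per type (default 10 CNA, 300
#'   methylation, 80 miRNA).
#' @param genes number of expression traits (default 100).
#' @param s true features per driven gene (default 3).
#' @param effect_range magnitude range of true coefficients, drawn
#'   uniformly with random sign (default `c(0.3, 1)`).
#' @param noise_sd trait noise standard deviation sigma (default 1).
#' @param cross_type_rho latent correlation between a single-type-driven
#'   gene's causal features and their designated partner features in other
#'   types, in `[0, 1)` (default 0.7).
#' @param frac_null fraction of genes driven by nothing (default 0.1).
#' @param frac_multi fraction of genes driven by exactly two feature
#'   types (default 0.4); the remainder are single-type-driven. No gene
#'   is genuinely driven by all three types, so the all-three Venn class
#'   of any analysis is entirely spurious by construction.
#' @param cna_probs category probabilities for the CNA calls -2..2
#'   (default `c(0.05, 0.15, 0.6, 0.15, 0.05)`, mass at 0).
#' @param meth_logit_scale scale of the latent Gaussian on the logit scale
#'   for methylation beta-values (default 1.5).
#' @param archetypes link trait mean/variance structure to the driving
#'   type (default TRUE): CNA-driven genes get high mean offsets,
#'   methylation-driven genes get amplified effects (hence higher trait
#'   variance).
#' @param seed integer seed; the generator is a pure function of this
#'   configuration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(N = 200,
                       J = c(CNA = 10, methylation = 300, miRNA = 80),
                       genes = 100, s = 3, effect_range = c(0.3, 1),
                       noise_sd = 1, cross_type_rho = 0.7,
                       frac_null = 0.1, frac_multi = 0.4,
                       cna_probs = c(0.05, 0.15, 0.6, 0.15, 0.05),
                       meth_logit_scale = 1.5, archetypes = TRUE,
                       seed = 1) {
  stopifnot(N >= 2, genes >= 1, s >= 1,
            all(names(J) %in% OMICS_TYPES), length(J) >= 1, all(J >= 1),
            length(effect_range) == 2, effect_range[1] > 0,
            effect_range[2] >= effect_range[1],
            noise_sd >= 0, cross_type_rho >= 0, cross_type_rho < 1,
            frac_null >= 0, frac_null <= 1, frac_multi >= 0,
            frac_multi <= 1, frac_null + frac_multi <= 1,
            length(cna_probs) == 5, all(cna_probs > 0),
            abs(sum(cna_probs) - 1) < 1e-8, meth_logit_scale > 0,
            seed == as.integer(seed))
  if (s > min(J))
    stop("infeasible: s = ", s, " exceeds the smallest block (",
         min(J), " features)")
  J <- J[intersect(OMICS_TYPES, names(J))]
  structure(list(N = as.integer(N), J = J, genes = as.integer(genes),
                 s = as.integer(s), effect_range = effect_range,
                 noise_sd = noise_sd, cross_type_rho = cross_type_rho,
                 frac_null = frac_null, frac_multi = frac_multi,
                 cna_probs = cna_probs,
                 meth_logit_scale = meth_logit_scale,
                 archetypes = isTRUE(archetypes), seed = as.integer(seed)),
            class = "sim_config")
}

feature_names <- function(J) {
  prefix <- c(CNA = "cna", methylation = "meth", miRNA = "mir")
  lapply(setNames(names(J), names(J)), function(ty)
    sprintf("%s_%03d", prefix[[ty]], seq_len(J[[ty]])))
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' Draws feature matrices with the type-specific marginals described in
#' [sim_config()], designates correlated cross-type feature pairs for the
#' causal features of single-type-driven genes (shared latent factors at
#' `cross_type_rho`), and builds each driven trait from its true
#' coefficients on the z-scored features plus `N(0, noise_sd^2)` noise.
#' The returned blocks are on the raw scale, so they pass the same
#' validation as data read from disk; normalize with
#' [normalize_dataset()] before fitting.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an unnormalized `multiomics_dataset`) and
#'   `truth` (class `sim_truth`: long true-coefficient table `beta`, gene
#'   `roles` with driving types, the correlated-pair `registry`,
#'   `noise_sd` and the `config`).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  N <- config$N
  J <- config$J
  types <- names(J)
  fnames <- feature_names(J)
  Jtot <- sum(J)
  all_ids <- unlist(fnames, use.names = FALSE)
  all_types <- rep(types, unname(J))
  samples <- sprintf("S%03d", seq_len(N))
  gene_ids <- sprintf("gene%03d", seq_len(config$genes))

  ## gene roles
  G <- config$genes
  n_null <- round(config$frac_null * G)
  n_multi <- round(config$frac_multi * G)
  n_single <- G - n_null - n_multi
  roles <- sample(c(rep("null", n_null), rep("multi", n_multi),
                    rep("single", n_single)))
  driving <- vector("list", G)
  for (g in seq_len(G)) {
    driving[[g]] <- switch(roles[g],
      null = character(0),
      single = sample(types, 1),
      # multi-type genes are driven by exactly two types: no gene is
      # genuinely driven by all three, so the all-three Venn class is a
      # pure read-out of spurious synergy in the benchmark
      multi = sort(sample(types, min(2L, length(types)))))
  }

  ## causal features per gene: s features spread over the driving types
  causal <- vector("list", G)
  for (g in seq_len(G)) {
    dt <- driving[[g]]
    if (length(dt) == 0) { causal[[g]] <- integer(0); next }
    per <- rep(config$s %/% length(dt), length(dt))
    extra <- config$s %% length(dt)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    idx <- integer(0)
    for (ti in seq_along(dt)) {
      offs <- cumsum(c(0, unname(J)))[match(dt[ti], types)]
      idx <- c(idx, offs + sample.int(J[[dt[ti]]], per[ti]))
    }
    causal[[g]] <- sort(idx)
  }

  ## correlated cross-type pairs: each causal feature of a single-type
  ## gene gets one partner in another type. Partners are preferentially
  ## drawn from features that are causal for no gene; when that pool is
  ## exhausted (many genes, few features) a feature causal for *another*
  ## gene may serve as partner — cross-type correlation in real data does
  ## not respect causal roles. Each feature sits in at most one pair.
  causal_all <- sort(unique(unlist(causal)))
  paired <- integer(0)
  registry <- list()
  if (config$cross_type_rho > 0 && length(types) > 1) {
    turn <- 0L  # rotates the partner type even when a small type saturates
    for (g in which(roles == "single")) {
      dt <- driving[[g]]
      others <- setdiff(types, dt)
      for (f in causal[[g]]) {
        if (f %in% vapply(registry, `[[`, 1L, "feature")) next
        for (step in seq_along(others)) {
          ot <- others[1 + ((turn + step - 1) %% length(others))]
          cand <- setdiff(which(all_types == ot), c(paired, causal[[g]]))
          cand <- setdiff(cand, vapply(registry, `[[`, 1L, "feature"))
          pool <- setdiff(cand, causal_all)
          if (length(pool) == 0) pool <- cand
          if (length(pool) == 0) next
          p <- pool[sample.int(length(pool), 1)]
          paired <- c(paired, p)
          registry[[length(registry) + 1]] <-
            list(feature = as.integer(f), partner = as.integer(p),
                 rho = config$cross_type_rho)
          break
        }
        turn <- turn + 1L
      }
    }
  }

  ## latent Gaussians; partners share the causal feature's factor
  Z <- matrix(rnorm(N * Jtot), N, Jtot)
  for (pr in registry) {
    Z[, pr$partner] <- pr$rho * Z[, pr$feature] +
      sqrt(1 - pr$rho^2) * Z[, pr$partner]
  }

  ## marginal transforms per type
  X <- matrix(NA_real_, N, Jtot, dimnames = list(samples, all_ids))
  cna_cuts <- qnorm(cumsum(config$cna_probs))[1:4]
  for (j in seq_len(Jtot)) {
    ty <- all_types[j]
    if (ty == "CNA") {
      col <- as.numeric(cut(Z[, j], c(-Inf, cna_cuts, Inf),
                            labels = FALSE)) - 3
      # guard against degenerate constant columns at small N
      tries <- 0
      while (length(unique(col)) == 1 && tries < 10) {
        z2 <- rnorm(N)
        col <- as.numeric(cut(z2, c(-Inf, cna_cuts, Inf),
                              labels = FALSE)) - 3
        tries <- tries + 1
      }
      X[, j] <- col
    } else if (ty == "methylation") {
      m0 <- runif(1, -1, 1)
      X[, j] <- plogis(config$meth_logit_scale * Z[, j] + m0)
    } else {
      X[, j] <- runif(1, -2, 2) + Z[, j]
    }
  }

  ## traits from true coefficients on the z-scored features
  Xz <- scale_pop(X)
  beta_rows <- list()
  expr <- matrix(NA_real_, G, N, dimnames = list(gene_ids, samples))
  for (g in seq_len(G)) {
    idx <- causal[[g]]
    b <- numeric(length(idx))
    if (length(idx)) {
      b <- runif(length(idx), config$effect_range[1],
                 config$effect_range[2]) *
        sample(c(-1, 1), length(idx), replace = TRUE)
      if (config$archetypes && identical(driving[[g]], "methylation"))
        b <- b * 1.8
    }
    offset <- if (config$archetypes && identical(driving[[g]], "CNA"))
      runif(1, 4, 8) else runif(1, 0, 2)
    y <- offset + rnorm(N, 0, config$noise_sd)
    if (length(idx)) y <- y + as.numeric(Xz[, idx, drop = FALSE] %*% b)
    expr[g, ] <- y
    if (length(idx))
      beta_rows[[g]] <- data.frame(
        gene_id = gene_ids[g], feature_id = all_ids[idx],
        feature_type = all_types[idx], beta = b, stringsAsFactors = FALSE)
  }
  beta <- do.call(rbind, c(beta_rows, list(make.row.names = FALSE)))
  if (is.null(beta))
    beta <- data.frame(gene_id = character(0), feature_id = character(0),
                       feature_type = character(0), beta = numeric(0),
                       stringsAsFactors = FALSE)

  blocks <- lapply(types, function(ty)
    omics_block(X[, all_types == ty, drop = FALSE], ty))
  dataset <- align_samples(blocks, expression_traits(expr))
  truth <- structure(list(
    beta = beta,
    roles = data.frame(gene_id = gene_ids, role = roles,
                       driving_types = vapply(driving, paste, "",
                                              collapse = "+"),
                       stringsAsFactors = FALSE),
    registry = if (length(registry)) data.frame(
      feature_id = all_ids[vapply(registry, `[[`, 1L, "feature")],
      feature_type = all_types[vapply(registry, `[[`, 1L, "feature")],
      partner_id = all_ids[vapply(registry, `[[`, 1L, "partner")],
      partner_type = all_types[vapply(registry, `[[`, 1L, "partner")],
      rho = vapply(registry, `[[`, 1, "rho"), stringsAsFactors = FALSE)
    else data.frame(feature_id = character(0), feature_type = character(0),
                    partner_id = character(0), partner_type = character(0),
                    rho = numeric(0), stringsAsFactors = FALSE),
    noise_sd = config$noise_sd, config = config), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

scale_pop <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(Xc^2) / nrow(X))
  s[s == 0] <- 1
  sweep(Xc, 2, s, "/")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes (%s), %d true coefficients, %d correlated pairs, sigma=%g\n",
              nrow(x$roles),
              paste(names(table(x$roles$role)), table(x$roles$role),
                    sep = "=", collapse = ", "),
              nrow(x$beta), nrow(x$registry), x$noise_sd))
  invisible(x)
}

#' Support-recovery metrics against simulated ground truth
#'
#' Compares the selected associations (at strength threshold `rho`)
#' with the true nonzero coefficients: precision, recall and F1 of the
#' support, overall and per feature type, and the RMSE of the estimated
#' coefficients on the true support (missed features count as estimates of
#' zero). With no selections, precision is undefined and returned `NA`.
#'
#' @param fit an `ieqtl` fit (or long coefficient table) on a simulated
#'   dataset.
#' @param truth the matching `sim_truth`.
#' @param rho strength threshold applied to the selections (default 0).
#' @return list with `overall` (precision, recall, f1, rmse_support,
#'   tp/fp/fn counts) and `by_type` (the same per feature type).
#' @export
recovery_metrics <- function(fit, truth, rho = 0) {
  stopifnot(inherits(truth, "sim_truth"))
  edges <- extract_edges(fit, rho = rho)
  sel_key <- paste(edges$gene_id, edges$feature_type, edges$feature_id,
                   sep = "\r")
  true_key <- paste(truth$beta$gene_id, truth$beta$feature_type,
                    truth$beta$feature_id, sep = "\r")
  est <- setNames(edges$signed_beta, sel_key)
  score <- function(sel, tru, est_beta, true_beta) {
    tp <- sum(sel %in% tru)
    fp <- sum(!(sel %in% tru))
    fn <- sum(!(tru %in% sel))
    precision <- if (length(sel)) tp / length(sel) else NA_real_
    recall <- if (length(tru)) tp / length(tru) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) &&
              (precision + recall) > 0)
      2 * precision * recall / (precision + recall) else
        if (length(tru) && length(sel)) 0 else NA_real_
    rmse <- if (length(tru)) {
      got <- est_beta[tru]
      got[is.na(got)] <- 0
      sqrt(mean((got - true_beta)^2))
    } else NA_real_
    c(precision = precision, recall = recall, f1 = f1,
      rmse_support = rmse, tp = tp, fp = fp, fn = fn)
  }
  overall <- score(sel_key, true_key, est, truth$beta$beta)
  by_type <- t(vapply(OMICS_TYPES, function(ty) {
    si <- edges$feature_type == ty
    ti <- truth$beta$feature_type == ty
    score(sel_key[si], true_key[ti], est, truth$beta$beta[ti])
  }, numeric(7)))
  list(overall = overall, by_type = by_type)
}

#' Benchmark: integrative versus single-type analysis on synthetic data
#'
#' Generates `n_replicates` datasets from `config` (with distinct derived
#' seeds), fits each in integrative mode and in all three single-type
#' modes, and tabulates per replicate: the all-three-types Venn class size
#' under each analysis (single-type analysis = union of the three separate
#' fits), the number of false-type edges (edges whose feature type is not
#' among the gene's true driving types), and optionally the mean
#' cross-validated prediction accuracy on multi-type-driven genes per mode
#' and the network modularity per analysis.
#'
#' @param config a [sim_config()] with `cross_type_rho > 0` for the
#'   spurious-association question.
#' @param n_replicates number of replicate datasets (default 30).
#' @param accuracy also compute per-mode CV prediction accuracies on
#'   multi-type-driven genes (expensive).
#' @param network also compute network modularity per analysis at
#'   `rho_network`.
#' @param rho_edges strength threshold for Venn/false-type edge counts
#'   (default 0: any selected association).
#' @param rho_network threshold for the network comparison (default 0.3).
#' @param control an [ieqtl_control()]; its seed is overridden per
#'   replicate.
#' @param seed master seed for the replicate stream.
#' @return data frame of class `spurious_benchmark`, one row per
#'   replicate.
#' @export
spurious_benchmark <- function(config, n_replicates = 30, accuracy = FALSE,
                               network = FALSE, rho_edges = 0,
                               rho_network = 0.3,
                               control = ieqtl_control(), seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  old <- local_seed(seed)
  rep_seeds <- sample.int(2147483646L, 2 * n_replicates)
  restore_seed(old)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- rep_seeds[2 * r - 1]
    sim <- simulate_multiomics(cfg)
    ds <- normalize_dataset(sim$dataset)
    ctl <- within_control(control, seed = rep_seeds[2 * r],
                          accuracy = FALSE)
    fit_int <- ieqtl(ds, "integrative", control = ctl)
    fit_single <- lapply(setNames(OMICS_TYPES, OMICS_TYPES), function(ty)
      ieqtl(ds, ty, control = ctl))
    e_int <- extract_edges(fit_int, rho = rho_edges)
    e_sgl <- do.call(rbind, c(lapply(fit_single, extract_edges,
                                     rho = rho_edges),
                              list(make.row.names = FALSE)))
    row <- data.frame(
      rep = r,
      venn_all3_integrative = all3_count(e_int),
      venn_all3_single = all3_count(e_sgl),
      false_edges_integrative = false_type_count(e_int, sim$truth),
      false_edges_single = false_type_count(e_sgl, sim$truth),
      n_edges_integrative = nrow(e_int),
      n_edges_single = nrow(e_sgl))
    if (network) {
      row$modularity_integrative <- net_modularity(e_int, rho_network)
      row$modularity_single <- net_modularity(e_sgl, rho_network)
    }
    if (accuracy) {
      multi <- sim$truth$roles$gene_id[sim$truth$roles$role == "multi"]
      multi <- intersect(multi, names(fit_int$fits))
      ctl_acc <- within_control(ctl, accuracy = TRUE)
      accs <- vapply(
        c(list(integrative = "integrative"),
          setNames(as.list(OMICS_TYPES), OMICS_TYPES)),
        function(md) {
          f <- ieqtl(ds, md, genes = multi, control = ctl_acc)
          a <- vapply(f$fits, `[[`, 1, "accuracy")
          mean(a, na.rm = TRUE)
        }, 1)
      row$acc_integrative <- accs[["integrative"]]
      row$acc_CNA <- accs[["CNA"]]
      row$acc_methylation <- accs[["methylation"]]
      row$acc_miRNA <- accs[["miRNA"]]
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("spurious_benchmark", "data.frame")
  out
}

all3_count <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  cl <- classify_genes(edges)
  unname(cl$counts[paste(OMICS_TYPES, collapse = "+")])
}

false_type_count <- function(edges, truth) {
  if (nrow(edges) == 0) return(0L)
  drv <- strsplit(setNames(truth$roles$driving_types,
                           truth$roles$gene_id), "+", fixed = TRUE)
  ok <- mapply(function(ty, g) ty %in% drv[[g]],
               edges$feature_type, edges$gene_id)
  sum(!ok)
}

net_modularity <- function(edges, rho) {
  net <- suppressWarnings(build_network(edges, rho = rho))
  if (igraph::ecount(net) == 0) return(NA_real_)
  topology_summary(net)$modularity
}

#' @export
print.spurious_benchmark <- function(x, ...) {
  cat(sprintf("<spurious_benchmark> %d replicates\n", nrow(x)))
  cat(sprintf(
    "  all-three Venn class: integrative < single in %d/%d replicates (medians %g vs %g)\n",
    sum(x$venn_all3_integrative < x$venn_all3_single), nrow(x),
    median(x$venn_all3_integrative), median(x$venn_all3_single)))
  cat(sprintf(
    "  false-type edges:     integrative < single in %d/%d replicates (medians %g vs %g)\n",
    sum(x$false_edges_integrative < x$false_edges_single), nrow(x),
    median(x$false_edges_integrative), median(x$false_edges_single)))
  if ("acc_integrative" %in% colnames(x)) {
    best_single <- pmax(x$acc_CNA, x$acc_methylation, x$acc_miRNA)
    cat(sprintf(
      "  CV accuracy (multi-type genes): integrative >= best single in %d/%d replicates\n",
      sum(x$acc_integrative >= best_single), nrow(x)))
  }
  if ("modularity_integrative" %in% colnames(x)) {
    ok <- !is.na(x$modularity_integrative) & !is.na(x$modularity_single)
    cat(sprintf(
      "  network modularity:   integrative > single in %d/%d replicates\n",
      sum(x$modularity_integrative[ok] > x$modularity_single[ok]),
      sum(ok)))
  }
  invisible(x)
}

#' Write simulated ground truth as TSV + JSON
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(truth$beta, file.path(dir, "truth_beta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$roles, file.path(dir, "truth_roles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$registry, file.path(dir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(noise_sd = truth$noise_sd,
                            config = unclass(truth$config)),
                       file.path(dir, "truth_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
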