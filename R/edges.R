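## Analytics over fitted coefficients: thresholded edges, Venn classes,
## decile accuracy summaries, top-K relative contribution, hub features and
## cis flags. Everything here is a pure function of the fit table and the
## configuration, with deterministic tie-breaks, so reruns yield identical
## tables.

as_edge_source <- function(x) {
  if (inherits(x, "ieqtl")) return(coef(x))
  if (is.data.frame(x)) {
    need <- c("gene_id", "feature_id", "feature_type", "beta", "p_value")
    if (!all(need %in% colnames(x)))
      stop("edge source must have columns: ", paste(need, collapse = ", "))
    return(x)
  }
  stop("expected an 'ieqtl' fit or a coefficient data frame")
}

#' Extract thresholded association edges from a fit
#'
#' One edge per (gene, feature) pair with a nonzero clean-stage coefficient
#' whose magnitude (the association strength) is at least `rho`. Edges are
#' stably sorted by decreasing strength, then gene id, then feature id, so
#' top-K selections are deterministic.
#'
#' @param x an `ieqtl` fit or a long coefficient data frame (see
#'   [coef.ieqtl()]).
#' @param rho nonnegative strength threshold (0 keeps every nonzero
#'   coefficient).
#' @return data frame of class `assoc_edges` with columns `feature_id`,
#'   `feature_type`, `gene_id`, `strength`, `signed_beta`, `p_value`,
#'   `is_cis` (initialised `NA`), and attribute `rho`.
#' @export
extract_edges <- function(x, rho = 0) {
  stopifnot(is.numeric(rho), length(rho) == 1, rho >= 0)
  cf <- as_edge_source(x)
  cf <- cf[!is.na(cf$beta) & cf$beta != 0 & abs(cf$beta) >= rho, ,
           drop = FALSE]
  edges <- data.frame(feature_id = cf$feature_id,
                      feature_type = cf$feature_type,
                      gene_id = cf$gene_id,
                      strength = abs(cf$beta),
                      signed_beta = cf$beta,
                      p_value = cf$p_value,
                      is_cis = rep(NA, nrow(cf)),
                      stringsAsFactors = FALSE)
  ord <- order(-edges$strength, edges$gene_id, edges$feature_id,
               method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "rho") <- rho
  class(edges) <- c("assoc_edges", "data.frame")
  edges
}

venn_class_levels <- function() {
  combos <- unlist(lapply(1:3, function(k)
    apply(combn(OMICS_TYPES, k), 2, paste, collapse = "+")), use.names = FALSE)
  combos
}

#' Classify genes by the feature types they associate with
#'
#' Every gene with at least one edge is assigned to exactly one of the 7
#' classes of the three-set Venn partition (single types, pairs, all
#' three); the class counts therefore sum to the number of genes having any
#' edge. Genes whose class involves more than one type are the
#' "synergistic" genes.
#'
#' @param edges an edge table from [extract_edges()].
#' @return list with `genes` (data frame `gene_id`, `venn_class`) and
#'   `counts` (named integer vector over all 7 classes, zeros included).
#' @export
classify_genes <- function(edges) {
  lv <- venn_class_levels()
  if (nrow(edges) == 0) {
    return(list(genes = data.frame(gene_id = character(0),
                                   venn_class = character(0),
                                   stringsAsFactors = FALSE),
                counts = setNames(integer(length(lv)), lv)))
  }
  types_by_gene <- tapply(edges$feature_type, edges$gene_id, function(t)
    paste(intersect(OMICS_TYPES, unique(t)), collapse = "+"))
  genes <- data.frame(gene_id = names(types_by_gene),
                      venn_class = as.character(types_by_gene),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id, method = "radix"), , drop = FALSE]
  rownames(genes) <- NULL
  counts <- table(factor(genes$venn_class, levels = lv))
  list(genes = genes, counts = setNames(as.integer(counts), lv))
}

#' Decile-wise prediction accuracy and association counts
#'
#' Ranks genes by a per-gene expression statistic (mean `mu`, standard
#' deviation `sigma`, or their ratio `mu/sigma`), partitions them into
#' `n_bins` contiguous equal-sized bins (any remainder is distributed to
#' the lowest bins; ties in the statistic are broken by gene id), and
#' reports, per bin, the number of genes with at least one association of
#' strength `>= rho` and the mean cross-validated prediction accuracy over
#' those genes.
#'
#' @param fit an `ieqtl` fit (ideally fitted with `accuracy = TRUE`), or a
#'   long results table (as written by [write_results()]) for a single
#'   mode, in which case `expression` must be supplied.
#' @param stat one of `"mu"`, `"sigma"`, `"mu_over_sigma"`.
#' @param n_bins number of bins (default 10).
#' @param rho strength threshold applied before counting/averaging
#'   (default 0.1).
#' @param expression an [expression_traits()] object supplying the
#'   per-gene statistics when `fit` is a plain table.
#' @return data frame with one row per bin: `bin`, `n_genes`,
#'   `stat_median`, `n_with_assoc`, `mean_accuracy`.
#' @export
decile_analysis <- function(fit, stat = c("mu", "sigma", "mu_over_sigma"),
                            n_bins = 10, rho = 0.1, expression = NULL) {
  stat <- match.arg(stat)
  if (inherits(fit, "ieqtl")) {
    ids <- names(fit$fits)
    gs <- fit$gene_stats[match(ids, fit$gene_stats$gene_id), ,
                         drop = FALSE]
    acc <- setNames(vapply(fit$fits, `[[`, 1, "accuracy"), ids)
  } else {
    tab <- as_edge_source(fit)
    if (is.null(expression) || !inherits(expression, "expression_traits"))
      stop("'expression' (an expression_traits object) is required when ",
           "'fit' is a plain results table")
    ids <- sort(unique(tab$gene_id))
    if (!all(ids %in% expression$gene_ids))
      stop("results mention genes absent from 'expression'")
    gs <- data.frame(gene_id = ids,
                     mu = unname(expression$mu[ids]),
                     sigma = unname(expression$sigma[ids]),
                     stringsAsFactors = FALSE)
    acc <- setNames(tab$accuracy[match(ids, tab$gene_id)], ids)
  }
  n <- nrow(gs)
  if (n < n_bins)
    stop(sprintf("fewer genes (%d) than bins (%d)", n, n_bins))
  s <- switch(stat, mu = gs$mu, sigma = gs$sigma,
              mu_over_sigma = gs$mu / gs$sigma)
  ord <- order(s, gs$gene_id, method = "radix")
  gs <- gs[ord, , drop = FALSE]
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- rep(seq_len(n_bins), sizes)
  edges <- extract_edges(fit, rho = rho)
  assoc_genes <- unique(edges$gene_id)
  out <- data.frame(bin = seq_len(n_bins), n_genes = sizes,
                    stat_median = tapply(s[ord], bin, median),
                    n_with_assoc = NA_integer_, mean_accuracy = NA_real_,
                    row.names = NULL)
  for (b in seq_len(n_bins)) {
    ids <- gs$gene_id[bin == b]
    with_assoc <- ids[ids %in% assoc_genes]
    out$n_with_assoc[b] <- length(with_assoc)
    a <- acc[with_assoc]
    a[is.na(a)] <- 0  # undefined accuracies count as 0 in aggregates
    if (length(a)) out$mean_accuracy[b] <- mean(a)
  }
  attr(out, "stat") <- stat
  attr(out, "rho") <- rho
  out
}

#' Relative contribution of each feature type among the top-K associations
#'
#' For each `K`, takes the `min(K, |edges|)` strongest edges (the edge
#' table's sort order) and computes, among the distinct (gene, feature
#' type) pairs present, the proportion attributable to each type — so a
#' gene with several methylation edges counts once for methylation. The
#' proportions sum to 1 for every `K`.
#'
#' @param edges an edge table from [extract_edges()].
#' @param K_list strictly increasing positive integers.
#' @return data frame with columns `K`, `feature_type`, `proportion`,
#'   `n_pairs`. With an empty edge table all proportions are `NA`.
#' @export
top_k_contribution <- function(edges,
                               K_list = c(100, 200, 400, 800, 1600, 3200,
                                          6400)) {
  stopifnot(all(K_list > 0), !is.unsorted(K_list, strictly = TRUE))
  rows <- lapply(K_list, function(K) {
    top <- head(edges, min(K, nrow(edges)))
    if (nrow(top) == 0)
      return(data.frame(K = K, feature_type = OMICS_TYPES,
                        proportion = NA_real_, n_pairs = 0L,
                        stringsAsFactors = FALSE))
    pairs <- unique(top[, c("gene_id", "feature_type")])
    tab <- table(factor(pairs$feature_type, levels = OMICS_TYPES))
    data.frame(K = K, feature_type = OMICS_TYPES,
               proportion = as.numeric(tab) / nrow(pairs),
               n_pairs = as.integer(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Hub features: features associated with the most genes
#'
#' Ranks features by the number of distinct associated genes (degree in the
#' bipartite association network), ties broken by feature id, and attaches
#' the associated gene list per hub for export to external enrichment
#' tools.
#'
#' @param edges a non-empty edge table from [extract_edges()].
#' @param top_n how many hubs to return (default 10).
#' @return data frame `feature_id`, `feature_type`, `degree`, with the
#'   per-hub gene lists in attribute `genes` (a named list of sorted gene
#'   ids).
#' @export
hub_features <- function(edges, top_n = 10) {
  if (nrow(edges) == 0) stop("empty edge table")
  key <- paste(edges$feature_type, edges$feature_id, sep = "|")
  genes_by_feature <- tapply(edges$gene_id, key,
                             function(g) sort(unique(g)), simplify = FALSE)
  deg <- vapply(genes_by_feature, length, 1L)
  fid <- sub("^[^|]*\\|", "", names(deg))
  fty <- sub("\\|.*$", "", names(deg))
  ord <- order(-deg, fid, method = "radix")
  keep <- head(ord, top_n)
  out <- data.frame(feature_id = fid[keep], feature_type = fty[keep],
                    degree = as.integer(deg[keep]), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "genes") <- setNames(genes_by_feature[keep], out$feature_id)
  out
}

#' Flag trivial cis associations
#'
#' An edge is cis when its methylation feature maps to the gene it is
#' associated with; the default map is symbol identity (a methylation
#' feature named like its gene). CNA and miRNA edges are never cis under
#' the default rule. Unmapped methylation features are flagged trans and
#' counted.
#'
#' @param edges an edge table.
#' @param feature_to_gene optional named character vector mapping
#'   methylation feature ids to gene ids; defaults to the identity map.
#' @return the edge table with `is_cis` filled in and attributes `n_cis`,
#'   `n_trans`, `n_unmapped`.
#' @export
flag_cis_associations <- function(edges, feature_to_gene = NULL) {
  is_meth <- edges$feature_type == "methylation"
  if (is.null(feature_to_gene)) {
    mapped <- edges$feature_id
    unmapped <- rep(FALSE, nrow(edges))
  } else {
    mapped <- unname(feature_to_gene[edges$feature_id])
    unmapped <- is_meth & is.na(mapped)
  }
  edges$is_cis <- is_meth & !unmapped & mapped == edges$gene_id
  edges$is_cis[is.na(edges$is_cis)] <- FALSE
  attr(edges, "n_cis") <- sum(edges$is_cis)
  attr(edges, "n_trans") <- sum(!edges$is_cis)
  attr(edges, "n_unmapped") <- sum(unmapped)
  edges
}

#' Write fit results as a long TSV table plus a JSON run manifest
#'
#' One row per selected association; fitted genes with an empty selection
#' contribute a single row with `NA` feature fields so downstream decile
#' counts can see them.
#'
#' @param fit an `ieqtl` fit.
#' @param path output TSV path; the manifest is written next to it with
#'   extension `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "ieqtl"))
  rows <- lapply(fit$fits, function(f) {
    base <- data.frame(gene_id = f$gene_id, mode = f$mode,
                       lambda = f$lambda, accuracy = f$accuracy,
                       stringsAsFactors = FALSE)
    if (nrow(f$selected) == 0)
      return(cbind(base, feature_id = NA_character_,
                   feature_type = NA_character_, beta = NA_real_,
                   p_value = NA_real_))
    cbind(base[rep(1, nrow(f$selected)), , drop = FALSE], f$selected)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- tab[, c("gene_id", "mode", "feature_id", "feature_type", "beta",
                 "p_value", "lambda", "accuracy")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(mode = fit$mode, n_genes = length(fit$fits),
                   n_samples = fit$N, skipped = fit$skipped,
                   failures = fit$failures,
                   control = unclass(fit$control),
                   package_version = as.character(utils::packageVersion("inteqtl")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a long results table written by [write_results()]
#'
#' @param path TSV path.
#' @return a data frame usable by [extract_edges()] (rows with `NA`
#'   features are kept so gene-level metadata survives the round trip).
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
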