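## Containers and loaders for the heterogeneous feature blocks and the
## expression trait matrix. Feature files on disk are features x samples
## (first column feature ids, first row sample ids); in memory every block
## is stored samples x features so design matrices can be built by column
## binding.

#' Construct an omics feature block
#'
#' An `omics_block` holds one feature-type matrix in samples-by-features
#' orientation, with unique sample and feature identifiers and a flag
#' recording whether columns have been z-score normalized.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique non-empty dimnames. All entries must be finite.
#' @param type_label one of `"CNA"`, `"methylation"`, `"miRNA"`.
#' @param normalized logical; `TRUE` only when every column has mean 0 and
#'   population standard deviation 1.
#' @return an object of class `omics_block`.
#' @details Unnormalized CNA blocks are validated to contain only the GISTIC
#'   call categories -2, -1, 0, 1, 2.
#' @export
omics_block <- function(values, type_label, normalized = FALSE) {
  type_label <- match.arg(type_label, OMICS_TYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 colnames(values)[bad[2]], rownames(values)[bad[1]]))
  }
  if (type_label == "CNA" && !normalized &&
      !all(values %in% c(-2, -1, 0, 1, 2))) {
    badm <- matrix(!(values %in% c(-2, -1, 0, 1, 2)), nrow(values))
    bad <- which(badm, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "CNA value %g at feature '%s', sample '%s' outside {-2,-1,0,1,2}",
      values[bad[1], bad[2]], colnames(values)[bad[2]],
      rownames(values)[bad[1]]))
  }
  structure(list(type_label = type_label, values = values,
                 normalized = isTRUE(normalized)),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> type=%s  %d samples x %d features  %s\n",
              x$type_label, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

feature_ids <- function(block) colnames(block$values)
block_samples <- function(block) rownames(block$values)

#' Read a feature matrix from a tab-separated file
#'
#' Expects features in rows and samples in columns: the first row holds
#' sample ids, the first column feature ids, and the body is numeric.
#' The returned block is transposed to samples-by-features and is not
#' normalized.
#'
#' @param path path to a TSV file.
#' @param type_label feature type, one of `"CNA"`, `"methylation"`,
#'   `"miRNA"`.
#' @return an [omics_block()].
#' @export
read_feature_matrix <- function(path, type_label) {
  raw <- read_id_matrix(path)
  omics_block(t(raw), type_label = type_label, normalized = FALSE)
}

# shared TSV reader: features x samples with ids; errors name the offending
# row/column
read_id_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", row.names = NULL)
  if (ncol(df) < 2) stop("expected id column plus at least one sample: ",
                         path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' in %s",
                 ids[bad[1, 1]], samples[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, samples)
  num
}

#' Remove low-variance features from a block
#'
#' Drops features whose variance falls strictly below the `lower_quantile`
#' empirical quantile of the per-feature variances, computed on the raw
#' (unnormalized) scale. With distinct variances, `ceil((1 - q) * J)`
#' features are kept. Filtering is only defined before normalization (after
#' z-scoring every variance is 1).
#'
#' @param block an unnormalized [omics_block()].
#' @param lower_quantile fraction in `[0, 1)`; default 0.25 for methylation
#'   blocks and 0 otherwise, mirroring the convention of filtering only the
#'   large methylation feature set.
#' @return the filtered block.
#' @export
variance_filter <- function(block,
                            lower_quantile = if (block$type_label ==
                                                 "methylation") 0.25 else 0) {
  stopifnot(inherits(block, "omics_block"))
  if (block$normalized)
    stop("variance_filter must be applied before normalization ",
         "(pipeline order: filter on the raw scale, then z-score)")
  q <- lower_quantile
  if (!is.numeric(q) || length(q) != 1 || q < 0 || q >= 1)
    stop("'lower_quantile' must be a single value in [0, 1)")
  if (q == 0) return(block)
  v <- apply(block$values, 2, var)
  if (all(v == v[1]))
    stop("all features have identical variance; filtering at q > 0 ",
         "would be arbitrary")
  J <- length(v)
  n_drop <- J - as.integer(ceiling((1 - q) * J))
  if (n_drop <= 0) return(block)
  cutoff <- sort(v, method = "radix")[n_drop + 1]
  keep <- v >= cutoff  # drop strictly-below; ties at the cutoff survive
  omics_block(block$values[, keep, drop = FALSE], block$type_label,
              normalized = FALSE)
}

#' Z-score normalize the columns of a block
#'
#' Centers every feature to mean 0 and scales to standard deviation 1 using
#' the population convention (denominator N), so that for a standardized
#' column `x`, `crossprod(x) == N` exactly — convenient for lasso
#' stationarity checks. Idempotent up to floating point.
#'
#' @param block an [omics_block()] with no constant columns.
#' @return the normalized block with `normalized = TRUE`.
#' @export
zscore_normalize <- function(block) {
  stopifnot(inherits(block, "omics_block"))
  x <- block$values
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  s <- sqrt(colSums(xc^2) / n)
  if (any(s == 0))
    stop("constant feature(s) cannot be z-scored: ",
         paste(colnames(x)[s == 0], collapse = ", "))
  xs <- sweep(xc, 2, s, "/")
  out <- block
  out$values <- xs
  out$normalized <- TRUE
  out
}

#' Construct an expression-trait container
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique dimnames and finite entries.
#' @return an object of class `expression_traits` carrying per-gene mean
#'   `mu` and population standard deviation `sigma` across samples; genes
#'   with `sigma == 0` are flagged (they are skipped by [ieqtl()]).
#' @export
expression_traits <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("non-finite expression values")
  n <- ncol(values)
  mu <- rowMeans(values)
  sigma <- sqrt(rowSums((values - mu)^2) / n)
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), mu = mu, sigma = sigma,
                 zero_variance = rownames(values)[sigma == 0]),
            class = "expression_traits")
}

#' Read an expression matrix (genes x samples TSV)
#'
#' @param path path to a TSV file, first column gene ids, first row sample
#'   ids.
#' @return an [expression_traits()] object.
#' @export
read_expression_matrix <- function(path) {
  expression_traits(read_id_matrix(path))
}

#' @export
print.expression_traits <- function(x, ...) {
  cat(sprintf("<expression_traits> %d genes x %d samples (%d zero-variance)\n",
              nrow(x$values), ncol(x$values), length(x$zero_variance)))
  invisible(x)
}

#' Align feature blocks and expression to their common samples
#'
#' Restricts every input to the lexicographically sorted intersection of
#' sample ids and reorders all matrices identically, so the result does not
#' depend on the order of the input blocks or on sample permutations of any
#' input. A per-input report of dropped samples is attached.
#'
#' @param blocks a list of [omics_block()] objects (at most one per type).
#' @param expression an [expression_traits()] object.
#' @return a `multiomics_dataset`: list with `blocks` (named by type, in
#'   canonical CNA, methylation, miRNA order), `expression`, sample count
#'   `N`, type count `M`, and a `dropped` report.
#' @export
align_samples <- function(blocks, expression) {
  if (inherits(blocks, "omics_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, TRUE, "omics_block")),
            inherits(expression, "expression_traits"))
  types <- vapply(blocks, function(b) b$type_label, "")
  if (anyDuplicated(types))
    stop("more than one block of type: ",
         paste(unique(types[duplicated(types)]), collapse = ", "))
  sample_sets <- c(lapply(blocks, block_samples), list(expression$sample_ids))
  common <- Reduce(intersect, sample_sets)
  if (length(common) == 0) stop("no samples are shared by all inputs")
  common <- sort(common, method = "radix")
  dropped <- lapply(sample_sets, function(s) sort(setdiff(s, common)))
  names(dropped) <- c(types, "expression")
  blocks <- lapply(blocks, function(b) {
    b$values <- b$values[common, , drop = FALSE]
    b
  })
  names(blocks) <- types
  blocks <- blocks[intersect(OMICS_TYPES, types)]
  expr <- expression_traits(expression$values[, common, drop = FALSE])
  structure(list(blocks = blocks, expression = expr, N = length(common),
                 M = length(blocks), sample_ids = common, dropped = dropped),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> N=%d samples, M=%d feature types\n",
              x$N, x$M))
  for (b in x$blocks)
    cat(sprintf("  %-12s %5d features  %s\n", b$type_label,
                ncol(b$values), if (b$normalized) "normalized" else "raw"))
  cat(sprintf("  expression   %5d genes (%d zero-variance)\n",
              nrow(x$expression$values), length(x$expression$zero_variance)))
  invisible(x)
}

#' Z-score normalize every block of a dataset
#'
#' Applied after [align_samples()] so column statistics refer to the final
#' sample set. Expression traits are left on their original scale; they are
#' centered per gene at fit time (the model has no intercept) but not
#' variance-scaled, so coefficient magnitudes reflect trait scale.
#'
#' @param dataset a `multiomics_dataset`.
#' @return the dataset with all blocks normalized.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  dataset$blocks <- lapply(dataset$blocks, zscore_normalize)
  dataset
}

#' Convert a GISTIC "all_lesions"-style table to a CNA call block
#'
#' Extracts a cytoband-by-sample call matrix from the tab-separated lesion
#' table GISTIC writes: rows whose `Unique Name` mentions "CN values" are
#' skipped, the `Descriptor` column provides the cytoband id, and the
#' threshold calls in the sample columns are negated for deletion peaks so
#' the resulting matrix uses signed categories in \{-2,...,2\}.
#'
#' @param path path to the lesions table.
#' @return an unnormalized CNA [omics_block()].
#' @export
read_gistic_lesions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  need <- c("Unique Name", "Descriptor")
  if (!all(need %in% colnames(df)))
    stop("not a GISTIC lesions table (missing ",
         paste(setdiff(need, colnames(df)), collapse = ", "), "): ", path)
  df <- df[!grepl("CN values", df[["Unique Name"]], fixed = TRUE), ,
           drop = FALSE]
  meta <- c("Unique Name", "Descriptor", "Wide Peak Limits", "Peak Limits",
            "Region Limits", "q values",
            "Residual q values after removing segments shared with higher peaks",
            "Broad or Focal", "Amplitude Threshold")
  sample_cols <- setdiff(colnames(df), meta)
  sample_cols <- sample_cols[!grepl("^X?\\.*$|^$", sample_cols)]
  if (length(sample_cols) == 0) stop("no sample columns found in ", path)
  calls <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, sample_cols, drop = FALSE])),
           nrow = nrow(df)))
  if (anyNA(calls)) stop("non-numeric call values in ", path)
  sign <- ifelse(grepl("^Deletion", df[["Unique Name"]]), -1, 1)
  calls <- calls * sign
  cytoband <- trimws(df[["Descriptor"]])
  # a cytoband can host both an amplification and a deletion peak; keep the
  # call with the larger magnitude per (cytoband, sample)
  if (anyDuplicated(cytoband)) {
    keep <- !duplicated(cytoband)
    merged <- calls[keep, , drop = FALSE]
    rownames(merged) <- cytoband[keep]
    for (i in which(duplicated(cytoband))) {
      tgt <- cytoband[i]
      pick <- abs(calls[i, ]) > abs(merged[tgt, ])
      merged[tgt, pick] <- calls[i, pick]
    }
    calls <- merged
  } else {
    rownames(calls) <- cytoband
  }
  colnames(calls) <- sample_cols
  omics_block(t(calls), "CNA", normalized = FALSE)
}

#' Write a dataset as a directory of TSV matrices plus a JSON manifest
#'
#' Each block is written features-by-samples (the same layout
#' [read_feature_matrix()] reads); the manifest records sample order,
#' feature counts, normalization flags and md5 checksums.
#'
#' @param dataset a `multiomics_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (b in dataset$blocks) {
    f <- file.path(dir, paste0(tolower(b$type_label), ".tsv"))
    write_id_matrix(t(b$values), f)
    files[[b$type_label]] <- basename(f)
  }
  f <- file.path(dir, "expression.tsv")
  write_id_matrix(dataset$expression$values, f)
  files[["expression"]] <- basename(f)
  paths <- file.path(dir, unlist(files))
  manifest <- list(
    sample_ids = dataset$sample_ids,
    feature_counts = lapply(dataset$blocks, function(b) ncol(b$values)),
    n_genes = nrow(dataset$expression$values),
    normalized = lapply(dataset$blocks, function(b) b$normalized),
    files = files,
    md5 = as.list(setNames(unname(tools::md5sum(paths)), unlist(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a `multiomics_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  blocks <- list()
  for (ty in intersect(OMICS_TYPES, names(manifest$files))) {
    m <- read_id_matrix(file.path(dir, manifest$files[[ty]]))
    b <- omics_block(t(m), ty,
                     normalized = isTRUE(manifest$normalized[[ty]]))
    blocks[[ty]] <- b
  }
  expr <- read_expression_matrix(file.path(dir, manifest$files[["expression"]]))
  ds <- align_samples(unname(blocks), expr)
  ds
}

write_id_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- "feature_id"
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
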