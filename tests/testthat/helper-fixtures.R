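# shared fixture builders; everything is generated in code, nothing on disk

# standardized design matrix (population convention: crossprod(x) == n)
std_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X), "-")
  X <- sweep(X, 2, sqrt(colSums(X^2) / n), "/")
  colnames(X) <- sprintf("f%02d", seq_len(p))
  X
}

# a valid raw omics block
make_block <- function(n = 10, j = 4, type = "miRNA", seed = 1,
                       samples = sprintf("S%02d", seq_len(n))) {
  set.seed(seed)
  vals <- switch(type,
    CNA = matrix(sample(c(-2, -1, 0, 1, 2), n * j, replace = TRUE,
                        prob = c(.1, .2, .4, .2, .1)), n, j),
    methylation = matrix(plogis(rnorm(n * j)), n, j),
    miRNA = matrix(rnorm(n * j), n, j))
  dimnames(vals) <- list(samples,
                         sprintf("%s%02d", tolower(substr(type, 1, 2)),
                                 seq_len(j)))
  omics_block(vals, type)
}

# a small aligned, normalized three-block dataset with one designed trait:
# gene01 = b_cna * cna01 + b_meth * me01 (+ noise), gene02 pure noise
make_designed_dataset <- function(n = 100, j = c(4, 20, 8), b_cna = 1,
                                  b_meth = 0.8, noise = 0, seed = 3) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n))
  cna <- make_block(n, j[1], "CNA", seed = seed + 1, samples = samples)
  met <- make_block(n, j[2], "methylation", seed = seed + 2,
                    samples = samples)
  mir <- make_block(n, j[3], "miRNA", seed = seed + 3, samples = samples)
  zs <- function(x) {
    x <- x - mean(x)
    x / sqrt(mean(x^2))
  }
  y1 <- b_cna * zs(cna$values[, 1]) + b_meth * zs(met$values[, 1]) +
    rnorm(n, 0, noise)
  y2 <- rnorm(n)
  expr <- rbind(gene01 = y1, gene02 = y2)
  colnames(expr) <- samples
  ds <- align_samples(list(cna, met, mir), expression_traits(expr))
  normalize_dataset(ds)
}

# crafted edge table (already sorted the way extract_edges sorts)
make_edges <- function(feature_id, feature_type, gene_id, beta,
                       p_value = rep(0.01, length(beta))) {
  cf <- data.frame(gene_id = gene_id, feature_id = feature_id,
                   feature_type = feature_type, beta = beta,
                   p_value = p_value, stringsAsFactors = FALSE)
  extract_edges(cf, rho = 0)
}

# write a features x samples TSV
write_tsv_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
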