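# loading, validation, filtering and normalization of feature blocks

test_that("read_feature_matrix parses a features-x-samples TSV", {
  m <- matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("fA", "fB", "fC"), c("S1", "S2")))
  path <- write_tsv_matrix(m, tempfile(fileext = ".tsv"))
  b <- read_feature_matrix(path, "miRNA")
  expect_s3_class(b, "omics_block")
  expect_equal(dim(b), c(2L, 3L))  # samples x features
  expect_equal(b$values["S2", "fC"], 6)
  expect_false(b$normalized)
})

test_that("loader rejects bad input with informative errors", {
  m <- matrix(0:5, 3, 2, dimnames = list(c("fA", "fB", "fC"),
                                         c("S1", "S2")))
  # non-numeric cell named by feature and sample
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  df[2, "S2"] <- "oops"
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_matrix(path, "miRNA"), "fB.*S2")
  # duplicated feature id listed
  rownames(m) <- c("fA", "fA", "fC")
  path2 <- write_tsv_matrix(m, tempfile(fileext = ".tsv"))
  expect_error(read_feature_matrix(path2, "miRNA"), "fA")
  # CNA category set enforced
  cna <- matrix(c(-2, 0, 3, 1), 2, 2,
                dimnames = list(c("S1", "S2"), c("cb1", "cb2")))
  expect_error(omics_block(cna, "CNA"), "outside \\{-2,-1,0,1,2\\}")
  # non-finite entries rejected at load
  bad <- matrix(c(1, NA, 2, 3), 2, 2,
                dimnames = list(c("S1", "S2"), c("a", "b")))
  expect_error(omics_block(bad, "miRNA"), "non-finite")
})

test_that("variance_filter drops the lower-quantile features on raw scale", {
  # variances 1..8 -> q = 0.25 removes the two smallest, keeps 6
  set.seed(1)
  base <- scale(matrix(rnorm(40 * 8), 40, 8))  # unit variance columns
  vals <- sweep(base, 2, sqrt(1:8), "*")
  dimnames(vals) <- list(sprintf("S%02d", 1:40), sprintf("f%d", 1:8))
  b <- omics_block(vals, "methylation")
  f <- variance_filter(b, 0.25)
  expect_equal(ncol(f$values), 6L)
  expect_setequal(colnames(f$values), sprintf("f%d", 3:8))
  # q = 0 is the identity
  expect_identical(variance_filter(b, 0), b)
  # all-constant block cannot be filtered meaningfully
  const <- omics_block(matrix(5, 4, 3, dimnames = list(paste0("S", 1:4),
                                                       paste0("f", 1:3))),
                       "miRNA")
  expect_error(variance_filter(const, 0.25), "identical variance")
  # pipeline order is enforced: no filtering after normalization
  expect_error(variance_filter(zscore_normalize(make_block(20, 5)), 0.25),
               "before normalization")
})

test_that("zscore_normalize uses the population convention and is idempotent", {
  vals <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2,
                 dimnames = list(paste0("S", 1:3), c("a", "b")))
  z <- zscore_normalize(omics_block(vals, "miRNA"))
  expect_equal(z$values[, "a"],
               c(S1 = -1.22474487, S2 = 0, S3 = 1.22474487),
               tolerance = 1e-8)
  expect_true(z$normalized)
  # for standardized columns x'x == N exactly
  expect_equal(unname(colSums(z$values^2)), c(3, 3), tolerance = 1e-12)
  # idempotence
  z2 <- zscore_normalize(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  # constant column error names the feature
  cvals <- cbind(vals, cst = c(5, 5, 5))
  expect_error(zscore_normalize(omics_block(cvals, "miRNA")), "cst")
})

test_that("align_samples intersects, sorts, and is order invariant", {
  b1 <- make_block(5, 3, "CNA", seed = 1,
                   samples = c("C", "A", "B", "D", "E"))
  b2 <- make_block(4, 3, "methylation", seed = 2,
                   samples = c("B", "A", "Z", "C"))
  expr <- matrix(rnorm(6), 2, 3,
                 dimnames = list(c("g1", "g2"), c("B", "C", "A")))
  ds <- align_samples(list(b1, b2), expression_traits(expr))
  expect_equal(ds$sample_ids, c("A", "B", "C"))
  expect_equal(ds$N, 3L)
  expect_equal(names(ds$blocks), c("CNA", "methylation"))
  expect_equal(ds$dropped$CNA, c("D", "E"))
  # invariant to block order and to sample permutations of any input
  ds2 <- align_samples(list(b2, b1), expression_traits(expr))
  expect_equal(ds2$blocks$CNA$values, ds$blocks$CNA$values)
  expect_equal(ds2$expression$values, ds$expression$values)
  perm <- b1
  perm$values <- perm$values[c(4, 2, 5, 1, 3), , drop = FALSE]
  ds3 <- align_samples(list(perm, b2), expression_traits(expr))
  expect_equal(ds3$blocks$CNA$values, ds$blocks$CNA$values)
  # disjoint sample sets fail
  b3 <- make_block(3, 2, "miRNA", seed = 3,
                   samples = c("X1", "X2", "X3"))
  expect_error(align_samples(list(b1, b3), expression_traits(expr)),
               "no samples")
})

test_that("dataset TSV-directory round trip preserves values and flags", {
  ds <- make_designed_dataset(n = 30)
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_equal(back$sample_ids, ds$sample_ids)
  for (ty in names(ds$blocks)) {
    expect_equal(back$blocks[[ty]]$values, ds$blocks[[ty]]$values,
                 tolerance = 1e-12)
    expect_true(back$blocks[[ty]]$normalized)
  }
  expect_equal(back$expression$values, ds$expression$values,
               tolerance = 1e-12)
})

test_that("GISTIC lesions table converts to signed cytoband calls", {
  tab <- data.frame(
    "Unique Name" = c("Amplification Peak  1", "Deletion Peak  1",
                      "Amplification Peak  1 - CN values"),
    "Descriptor" = c("8q24.21", "9p21.3", "8q24.21"),
    "Wide Peak Limits" = "x", "Peak Limits" = "x", "Region Limits" = "x",
    "q values" = 0.01,
    "Residual q values after removing segments shared with higher peaks" = 0.01,
    "Broad or Focal" = "Focal", "Amplitude Threshold" = "0: t<0.1",
    "TCGA-01" = c(2, 1, 3.2), "TCGA-02" = c(0, 2, 0.1),
    check.names = FALSE)
  path <- tempfile(fileext = ".txt")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  b <- read_gistic_lesions(path)
  expect_equal(b$type_label, "CNA")
  expect_equal(sort(feature_ids <- colnames(b$values)),
               c("8q24.21", "9p21.3"))
  expect_equal(b$values["TCGA-01", "8q24.21"], 2)   # amplification kept
  expect_equal(b$values["TCGA-01", "9p21.3"], -1)   # deletion negated
  expect_equal(b$values["TCGA-02", "9p21.3"], -2)
})
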