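# association analytics: edges, Venn classes, deciles, top-K, hubs, cis

test_that("extract_edges thresholds, sorts, and is monotone in rho", {
  cf <- data.frame(gene_id = c("g1", "g1", "g2"),
                   feature_id = c("a", "b", "c"),
                   feature_type = c("CNA", "methylation", "miRNA"),
                   beta = c(0.05, 0.2, -0.35),
                   p_value = c(0.01, 0.02, 0.03))
  e <- extract_edges(cf, rho = 0.1)
  expect_equal(nrow(e), 2L)
  expect_equal(e$strength, c(0.35, 0.2))
  expect_equal(attr(e, "rho"), 0.1)
  # rho = 0 keeps every nonzero coefficient
  expect_equal(nrow(extract_edges(cf, rho = 0)), 3L)
  # equal strengths resolve by gene then feature id, stably
  tie <- data.frame(gene_id = c("g2", "g1"), feature_id = c("x", "y"),
                    feature_type = "miRNA", beta = c(0.5, 0.5),
                    p_value = 0.01)
  e2 <- extract_edges(tie, rho = 0)
  expect_equal(e2$gene_id, c("g1", "g2"))
  # monotone: edges at a higher threshold are a subset
  set.seed(1)
  cf3 <- data.frame(gene_id = sample(paste0("g", 1:8), 60, TRUE),
                    feature_id = paste0("f", 1:60),
                    feature_type = sample(c("CNA", "methylation", "miRNA"),
                                          60, TRUE),
                    beta = rnorm(60, 0, 0.4), p_value = runif(60))
  prev <- extract_edges(cf3, rho = 0)
  for (rho in c(0.1, 0.2, 0.4, 0.8)) {
    cur <- extract_edges(cf3, rho = rho)
    key <- function(d) paste(d$gene_id, d$feature_id)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("classify_genes produces a 7-class partition", {
  e <- make_edges(feature_id = c("a", "b", "c", "d", "e"),
                  feature_type = c("CNA", "miRNA", "methylation",
                                   "methylation", "CNA"),
                  gene_id = c("g1", "g1", "g2", "g2", "g3"),
                  beta = c(0.5, 0.4, 0.3, 0.2, 0.6))
  cl <- classify_genes(e)
  expect_equal(cl$genes$venn_class[cl$genes$gene_id == "g1"],
               "CNA+miRNA")
  expect_equal(cl$genes$venn_class[cl$genes$gene_id == "g2"],
               "methylation")
  expect_length(cl$counts, 7L)
  expect_equal(sum(cl$counts), length(unique(e$gene_id)))
  # partition property on random tables
  set.seed(2)
  cf <- data.frame(gene_id = sample(paste0("g", 1:15), 80, TRUE),
                   feature_id = paste0("f", 1:80),
                   feature_type = sample(c("CNA", "methylation", "miRNA"),
                                         80, TRUE),
                   beta = rnorm(80), p_value = runif(80))
  e2 <- extract_edges(cf, rho = 0)
  cl2 <- classify_genes(e2)
  expect_equal(sum(cl2$counts), length(unique(e2$gene_id)))
  expect_equal(nrow(cl2$genes), length(unique(e2$gene_id)))
})

test_that("decile bins are equal-sized with remainder to the lowest bins", {
  ds <- make_designed_dataset(n = 40)
  # build a fit-like results table for 23 genes with known stats
  set.seed(3)
  expr <- matrix(rnorm(23 * 40), 23, 40,
                 dimnames = list(sprintf("g%02d", 1:23),
                                 sprintf("S%03d", 1:40)))
  et <- expression_traits(expr)
  tab <- data.frame(gene_id = rownames(expr), mode = "integrative",
                    feature_id = "f1", feature_type = "miRNA",
                    beta = 0.5, p_value = 0.01, lambda = 1,
                    accuracy = seq(0, 1, length.out = 23))
  d <- decile_analysis(tab, stat = "mu", n_bins = 10, rho = 0.1,
                       expression = et)
  expect_equal(d$n_genes, c(3L, 3L, 3L, rep(2L, 7)))
  expect_equal(sum(d$n_genes), 23L)
  expect_equal(d$n_with_assoc, d$n_genes)  # every gene has an edge
  # fewer genes than bins is an error
  expect_error(decile_analysis(tab[1:5, ], stat = "mu", n_bins = 10,
                               expression = et), "fewer genes")
  # all-equal statistic falls back to gene-id order (deterministic)
  expr2 <- matrix(1, 12, 40,
                  dimnames = list(sprintf("h%02d", 1:12),
                                  sprintf("S%03d", 1:40)))
  expr2 <- expr2 + matrix(rnorm(12 * 40, 0, 1), 12, 40)
  expr2 <- expr2 - rowMeans(expr2)  # mu identical (0) for every gene
  et2 <- expression_traits(expr2)
  tab2 <- tab[1:12, ]
  tab2$gene_id <- rownames(expr2)
  d2 <- decile_analysis(tab2, stat = "mu", n_bins = 10, expression = et2)
  d3 <- decile_analysis(tab2, stat = "mu", n_bins = 10, expression = et2)
  expect_identical(d2, d3)
})

test_that("top-K contribution counts distinct gene-type pairs", {
  e <- make_edges(feature_id = c("a", "b", "c", "d"),
                  feature_type = c("CNA", "methylation", "methylation",
                                   "miRNA"),
                  gene_id = c("g1", "g2", "g3", "g4"),
                  beta = c(0.9, 0.8, 0.7, 0.6))
  t2 <- top_k_contribution(e, K_list = c(2, 10))
  k2 <- t2[t2$K == 2, ]
  expect_equal(k2$proportion[k2$feature_type == "CNA"], 0.5)
  expect_equal(k2$proportion[k2$feature_type == "methylation"], 0.5)
  expect_equal(k2$proportion[k2$feature_type == "miRNA"], 0)
  # K beyond the edge count clamps to the full table
  k10 <- t2[t2$K == 10, ]
  expect_equal(sum(k10$n_pairs), 4L)
  # one gene with several methylation edges counts once
  e2 <- make_edges(feature_id = c("m1", "m2", "m3"),
                   feature_type = "methylation", gene_id = "g1",
                   beta = c(0.9, 0.8, 0.7))
  t3 <- top_k_contribution(e2, K_list = 3)
  expect_equal(t3$proportion[t3$feature_type == "methylation"], 1)
  expect_equal(sum(t3$n_pairs), 1L)
  # proportions always sum to 1 on non-empty tables
  set.seed(4)
  cf <- data.frame(gene_id = sample(paste0("g", 1:9), 50, TRUE),
                   feature_id = paste0("f", 1:50),
                   feature_type = sample(c("CNA", "methylation", "miRNA"),
                                         50, TRUE),
                   beta = rnorm(50), p_value = runif(50))
  e3 <- extract_edges(cf, rho = 0)
  tk <- top_k_contribution(e3, K_list = c(1, 5, 25, 100))
  sums <- tapply(tk$proportion, tk$K, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("hub ranking counts distinct genes with stable tie-breaks", {
  e <- make_edges(feature_id = c("A", "A", "A", "A", "B", "C", "C"),
                  feature_type = "methylation",
                  gene_id = c("g1", "g2", "g3", "g3", "g4", "g5", "g6"),
                  beta = c(0.9, 0.8, 0.7, 0.65, 0.6, 0.5, 0.4))
  h <- hub_features(e, top_n = 3)
  expect_equal(h$feature_id, c("A", "C", "B"))  # 3, 2, 1 distinct genes
  expect_equal(h$degree, c(3L, 2L, 1L))
  expect_equal(attr(h, "genes")$A, c("g1", "g2", "g3"))
  expect_error(hub_features(e[0, ]), "empty")
})

test_that("cis flags use symbol identity for methylation only", {
  e <- make_edges(feature_id = c("SPRY4", "SPRY4", "m2"),
                  feature_type = c("methylation", "CNA", "methylation"),
                  gene_id = c("SPRY4", "SPRY4", "g9"),
                  beta = c(0.5, 0.4, 0.3))
  f <- flag_cis_associations(e)
  expect_equal(f$is_cis[f$feature_type == "methylation" &
                          f$gene_id == "SPRY4"], TRUE)
  expect_false(any(f$is_cis[f$feature_type == "CNA"]))
  expect_equal(attr(f, "n_cis"), 1L)
  # explicit map: unmapped methylation features stay trans and are counted
  f2 <- flag_cis_associations(e, feature_to_gene = c(m2 = "g9"))
  expect_true(f2$is_cis[f2$feature_id == "m2"])
  expect_equal(attr(f2, "n_unmapped"), 1L)
})
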