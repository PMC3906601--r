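# bipartite association network: construction, topology, export

two_k22 <- function() {
  # two disconnected 4-cycles (each a complete bipartite K_{2,2})
  make_edges(
    feature_id = c("f1", "f1", "f2", "f2", "f3", "f3", "f4", "f4"),
    feature_type = "miRNA",
    gene_id = c("g1", "g2", "g1", "g2", "g3", "g4", "g3", "g4"),
    beta = rep(0.5, 8))
}

test_that("build_network filters by rho and keeps only edge endpoints", {
  e <- make_edges(feature_id = c("a", "b", "c", "d", "e"),
                  feature_type = c("CNA", "methylation", "miRNA",
                                   "methylation", "CNA"),
                  gene_id = paste0("g", 1:5),
                  beta = c(0.5, 0.4, 0.35, 0.2, 0.1))
  net <- build_network(e, rho = 0.3)
  expect_equal(igraph::ecount(net), 3L)
  expect_equal(igraph::vcount(net), 6L)  # 3 features + 3 genes
  # rho = 0 keeps everything
  expect_equal(igraph::ecount(build_network(e, rho = 0)), 5L)
  # strictly bipartite: every edge joins a feature to a gene
  el <- igraph::as_edgelist(net)
  is_gene <- function(v) startsWith(v, "gene|")
  expect_true(all(xor(is_gene(el[, 1]), is_gene(el[, 2]))))
  # empty networks warn
  expect_warning(build_network(e, rho = 2), "empty")
})

test_that("two disconnected 4-cycles give modularity 1/2", {
  net <- build_network(two_k22(), rho = 0)
  topo <- topology_summary(net)
  expect_equal(topo$n_components, 2L)
  expect_equal(topo$component_sizes, c(4L, 4L))
  expect_equal(topo$modularity, 0.5, tolerance = 1e-9)
  # closed-form check of the same partition: e_ii - a_i^2 summed
  el <- igraph::as_edgelist(net)
  memb <- topo$membership
  expect_equal(modularity_closed_form(el[, 1], el[, 2], memb), 0.5,
               tolerance = 1e-12)
})

test_that("square clustering matches closed forms", {
  # complete bipartite K_{2,2}: every node has coefficient 1
  k22 <- build_network(two_k22(), rho = 0)
  expect_true(all(abs(square_clustering(k22) - 1) < 1e-12))
  # a star has no squares
  star <- make_edges(feature_id = "hub", feature_type = "miRNA",
                     gene_id = paste0("g", 1:5), beta = rep(0.5, 5))
  expect_true(all(square_clustering(build_network(star, rho = 0)) == 0))
  # a 6-cycle has neighbour pairs but no squares either
  six <- make_edges(feature_id = c("f1", "f2", "f2", "f3", "f3", "f1"),
                    feature_type = "CNA",
                    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
                    beta = rep(0.4, 6))
  expect_true(all(square_clustering(build_network(six, rho = 0)) == 0))
})

test_that("largest-component genes are extracted with deterministic ties", {
  e <- make_edges(feature_id = c("f1", "f1", "f1", "f2"),
                  feature_type = "methylation",
                  gene_id = c("g1", "g2", "g3", "g9"),
                  beta = rep(0.5, 4))
  net <- build_network(e, rho = 0)
  expect_equal(largest_component_genes(net), c("g1", "g2", "g3"))
  # tie between equal components: lexicographically smallest node set wins
  tie <- make_edges(feature_id = c("f1", "f2"), feature_type = "miRNA",
                    gene_id = c("gB", "gA"), beta = c(0.5, 0.5))
  expect_equal(largest_component_genes(build_network(tie, rho = 0)),
               "gA")
  # a bipartite network without isolated nodes always has gene nodes in
  # its largest component
  expect_gt(length(largest_component_genes(build_network(two_k22(), 0))),
            0)
})

test_that("export/import round-trips preserve the network", {
  e <- make_edges(feature_id = c("f1", "f2", "f1"),
                  feature_type = c("CNA", "miRNA", "CNA"),
                  gene_id = c("g1", "g1", "g2"),
                  beta = c(0.9, -0.5, 0.4),
                  p_value = c(0.001, 0.02, 0.04))
  net <- build_network(e, rho = 0)
  key <- function(g) {
    tab <- inteqtl:::network_edge_table(g)
    tab[order(tab$feature_id, tab$gene_id), ]
  }
  for (fmt in c("tsv", "graphml")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_network(net, path, format = fmt)
    back <- import_network(path, format = fmt)
    expect_equal(key(back)[c("feature_id", "feature_type", "gene_id",
                             "weight", "p_value")],
                 key(net)[c("feature_id", "feature_type", "gene_id",
                            "weight", "p_value")],
                 tolerance = 1e-12)
    expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
    expect_setequal(igraph::V(back)$node_type, igraph::V(net)$node_type)
  }
  # SIF carries topology and feature types (no weights by design)
  path <- tempfile(fileext = ".sif")
  export_network(net, path, format = "sif")
  lines <- readLines(path)
  expect_length(lines, 3L)
  back <- import_network(path, format = "sif")
  expect_equal(key(back)[c("feature_id", "feature_type", "gene_id")],
               key(net)[c("feature_id", "feature_type", "gene_id")])
  # exports are byte-stable across repeated calls
  p1 <- tempfile(); p2 <- tempfile()
  export_network(net, p1, "tsv"); export_network(net, p2, "tsv")
  expect_identical(readLines(p1), readLines(p2))
  expect_error(export_network(net, tempfile(), "dot"))
})
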