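## Heterogeneous (bipartite feature-gene) association network. igraph
## supplies the graph container, connected components, GraphML IO and
## greedy modularity optimisation; the square-based clustering coefficient
## for bipartite graphs (triangles cannot exist, so the usual coefficient
## is identically zero) is computed here directly.
##
## Internal vertex names are "type|id" for features and "gene|id" for
## genes, because a methylation feature may carry the same symbol as its
## gene; raw identifiers are kept in the vertex attribute "label" and the
## type in "node_type".

#' Build the bipartite association network
#'
#' Nodes are genomic features (typed CNA/methylation/miRNA) and genes;
#' every edge joins a feature to a gene and is weighted by association
#' strength. Edges weaker than `rho` are discarded and isolated nodes are
#' removed (only edge endpoints become nodes).
#'
#' @param edges an edge table from [extract_edges()].
#' @param rho strength threshold (default 0.3, the network-view
#'   convention; analytics use 0.1).
#' @return an `igraph` graph with vertex attributes `label` (raw id) and
#'   `node_type` (`gene` or a feature type), edge attributes `weight`,
#'   `signed_beta`, `p_value`, and graph attribute `rho`. Empty networks
#'   are allowed (with a warning).
#' @export
build_network <- function(edges, rho = 0.3) {
  stopifnot(is.numeric(rho), rho >= 0)
  keep <- edges[edges$strength >= rho, , drop = FALSE]
  if (nrow(keep) == 0)
    warning("no edges at or above rho = ", rho, "; network is empty")
  feat <- sprintf("%s|%s", keep$feature_type, keep$feature_id)
  gene <- sprintf("gene|%s", keep$gene_id)
  el <- data.frame(from = feat, to = gene,
                   weight = keep$strength,
                   signed_beta = keep$signed_beta,
                   p_value = keep$p_value, stringsAsFactors = FALSE)
  verts <- unique(data.frame(
    name = c(feat, gene),
    label = c(keep$feature_id, keep$gene_id),
    node_type = c(keep$feature_type, rep("gene", nrow(keep))),
    stringsAsFactors = FALSE))
  verts <- verts[order(verts$name, method = "radix"), , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = verts)
  g <- igraph::set_graph_attr(g, "rho", rho)
  g
}

#' Square-based clustering coefficient for bipartite graphs
#'
#' The fraction of potential squares (4-cycles) through each node that are
#' realised — the bipartite analogue of the triangle clustering
#' coefficient. Nodes with no neighbour pairs, or no potential squares,
#' score 0.
#'
#' @param graph an undirected `igraph` graph.
#' @return named numeric vector, one coefficient per vertex.
#' @export
square_clustering <- function(graph) {
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  nv <- igraph::vcount(graph)
  deg <- lengths(adj)
  out <- numeric(nv)
  for (v in seq_len(nv)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    num <- 0
    den <- 0
    for (a in seq_len(length(nb) - 1)) {
      u <- nb[a]
      for (b in seq((a + 1), length(nb))) {
        w <- nb[b]
        q <- length(setdiff(intersect(adj[[u]], adj[[w]]), v))
        theta <- as.integer(w %in% adj[[u]])
        degm <- q + 1 + theta
        num <- num + q
        den <- den + (deg[u] - degm) + (deg[w] - degm) + q
      }
    }
    if (den > 0) out[v] <- num / den
  }
  names(out) <- igraph::V(graph)$name
  out
}

#' Topology diagnostics of an association network
#'
#' Connected components, the largest component (size ties broken by the
#' lexicographically smallest sorted node-name set), the mean square-based
#' bipartite clustering coefficient, and the Newman modularity Q of the
#' partition found by greedy agglomerative optimisation on the unweighted
#' graph.
#'
#' @param net a network from [build_network()].
#' @return list with `n_components`, `component_sizes` (decreasing),
#'   `largest_component` (node labels), `square_clustering` (per node),
#'   `mean_square_clustering`, `modularity`, `membership` (community id
#'   per node).
#' @export
topology_summary <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  largest <- largest_component_nodes(net, comp)
  sq <- square_clustering(net)
  # modularity is defined on the unweighted graph: drop the weight
  # attribute so igraph does not silently use it
  unw <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::delete_edge_attr(net, "weight") else net
  cl <- igraph::cluster_fast_greedy(unw)
  memb <- igraph::membership(cl)
  Q <- igraph::modularity(unw, memb)
  list(n_components = comp$no, component_sizes = sizes,
       largest_component = igraph::V(net)$label[comp$membership ==
                                                  largest],
       square_clustering = sq,
       mean_square_clustering = mean(sq),
       modularity = Q, membership = memb)
}

# id of the largest component; ties resolved by the lexicographically
# smallest sorted set of node names
largest_component_nodes <- function(net, comp = igraph::components(net)) {
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) == 1) return(cand)
  keys <- vapply(cand, function(ci)
    paste(sort(igraph::V(net)$name[comp$membership == ci]),
          collapse = "\r"), "")
  cand[order(keys, method = "radix")[1]]
}

#' Genes of the largest connected component
#'
#' @param net a network from [build_network()].
#' @return sorted character vector of gene ids in the maximum-size
#'   component (exported as a plain list for external enrichment tools).
#' @export
largest_component_genes <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  ci <- largest_component_nodes(net, comp)
  inside <- comp$membership == ci
  sort(igraph::V(net)$label[inside & igraph::V(net)$node_type == "gene"])
}

#' Export an association network to Cytoscape-compatible files
#'
#' Formats: `"sif"` (lines `feature_id <TAB> type <TAB> gene_id`; carries
#' no edge weights), `"graphml"` (full node/edge attributes), `"tsv"`
#' (edge list with weights and p-values). Output ordering is byte-stable.
#'
#' @param net a network from [build_network()].
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  el <- network_edge_table(net)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", el$feature_id, el$feature_type,
                     el$gene_id)
    writeLines(lines, path)
  } else if (format == "tsv") {
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

# deterministic long edge table of a network
network_edge_table <- function(net) {
  elm <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(elm) == 0)
    return(data.frame(feature_id = character(0),
                      feature_type = character(0),
                      gene_id = character(0), weight = numeric(0),
                      signed_beta = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  # orient every edge feature -> gene
  from_gene <- startsWith(elm[, 1], "gene|")
  feat <- ifelse(from_gene, elm[, 2], elm[, 1])
  gene <- ifelse(from_gene, elm[, 1], elm[, 2])
  out <- data.frame(
    feature_id = sub("^[^|]*\\|", "", feat),
    feature_type = sub("\\|.*$", "", feat),
    gene_id = sub("^[^|]*\\|", "", gene),
    weight = igraph::E(net)$weight,
    signed_beta = igraph::E(net)$signed_beta,
    p_value = igraph::E(net)$p_value, stringsAsFactors = FALSE)
  ord <- order(out$feature_type, out$feature_id, out$gene_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import a network exported by [export_network()]
#'
#' GraphML and TSV round-trips reproduce node sets, edge sets and
#' attributes exactly; SIF carries topology and feature types but no
#' weights (absent attributes come back `NA`).
#'
#' @param path file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return an `igraph` graph in the same internal representation as
#'   [build_network()] produces.
#' @export
import_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph stores the original name in "name"; drop its own added "id"
    if ("id" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "id")
    return(g)
  }
  if (format == "tsv") {
    el <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c(feature_id = "character",
                                    gene_id = "character"))
  } else {
    raw <- read.delim(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("feature_id", "feature_type",
                                    "gene_id"),
                      colClasses = "character")
    el <- data.frame(raw, weight = NA_real_, signed_beta = NA_real_,
                     p_value = NA_real_, stringsAsFactors = FALSE)
  }
  edges <- data.frame(feature_id = el$feature_id,
                      feature_type = el$feature_type,
                      gene_id = el$gene_id,
                      strength = el$weight,
                      signed_beta = el$signed_beta,
                      p_value = el$p_value, is_cis = NA,
                      stringsAsFactors = FALSE)
  feat <- sprintf("%s|%s", edges$feature_type, edges$feature_id)
  gene <- sprintf("gene|%s", edges$gene_id)
  eln <- data.frame(from = feat, to = gene, weight = edges$strength,
                    signed_beta = edges$signed_beta,
                    p_value = edges$p_value, stringsAsFactors = FALSE)
  verts <- unique(data.frame(
    name = c(feat, gene),
    label = c(edges$feature_id, edges$gene_id),
    node_type = c(edges$feature_type, rep("gene", nrow(edges))),
    stringsAsFactors = FALSE))
  verts <- verts[order(verts$name, method = "radix"), , drop = FALSE]
  igraph::graph_from_data_frame(eln, directed = FALSE, vertices = verts)
}
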