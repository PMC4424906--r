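#' Construct a tissue-specific interaction network
#'
#' A TS-PPI network is a node-weighted, edge-weighted simple undirected graph
#' over gene symbols, restricted to one tissue/tumor selection.  Node weights
#' are positive expression scores; edge weights lie in \[0, 1\] and edges may
#' carry a tissue label and a dataset-coverage value.
#'
#' @param nodes data frame with columns `gene` and `weight` (positive reals).
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`, and
#'   optionally `label` and `coverage`.  Both endpoints must appear in
#'   `nodes`; self-loops and duplicate pairs are rejected.
#' @param name network label.
#' @param conditions character vector of tissue/tumor names the network
#'   refers to.
#' @return An object of class `tsppi_network` wrapping an igraph graph.
#' @export
tsppi_network <- function(nodes, edges, name = "network",
                          conditions = character()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("gene", "weight") %in% names(nodes)))
    stop("'nodes' needs columns 'gene' and 'weight'")
  nodes$gene <- canonical_gene(as.character(nodes$gene))
  if (anyDuplicated(nodes$gene))
    stop("duplicate gene in node table: ",
         nodes$gene[duplicated(nodes$gene)][1L])
  if (nrow(nodes) > 0 && (any(!is.finite(nodes$weight)) || any(nodes$weight <= 0)))
    stop("node weights (expression scores) must be positive")
  if (nrow(edges) > 0) {
    if (!all(c("gene_a", "gene_b", "weight") %in% names(edges)))
      stop("'edges' needs columns 'gene_a', 'gene_b' and 'weight'")
    edges$gene_a <- canonical_gene(as.character(edges$gene_a))
    edges$gene_b <- canonical_gene(as.character(edges$gene_b))
    if (any(edges$gene_a == edges$gene_b))
      stop("self-loops are not allowed in a TS-PPI network")
    if (anyDuplicated(pair_key(edges$gene_a, edges$gene_b)))
      stop("parallel edges are not allowed in a TS-PPI network")
    if (any(!is.finite(edges$weight)) ||
        any(edges$weight < 0 | edges$weight > 1))
      stop("edge weights must lie in [0, 1]")
    missing_ep <- setdiff(c(edges$gene_a, edges$gene_b), nodes$gene)
    if (length(missing_ep) > 0)
      stop("edge endpoint without a node entry: ", missing_ep[1L])
    if (!"label" %in% names(edges)) edges$label <- NA_character_
    if (!"coverage" %in% names(edges)) edges$coverage <- NA_real_
    edges <- edges[, c("gene_a", "gene_b", "weight", "label", "coverage")]
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), label = character(),
                        coverage = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = nodes[, c("gene", "weight")])
  structure(list(name = name, conditions = as.character(conditions),
                 graph = g),
            class = "tsppi_network")
}

#' Node table of a TS-PPI network
#' @param net a `tsppi_network`.
#' @return data frame with columns `gene` and `weight`.
#' @export
tsppi_nodes <- function(net) {
  g <- net$graph
  data.frame(gene = igraph::V(g)$name,
             weight = igraph::V(g)$weight,
             stringsAsFactors = FALSE)
}

#' Edge table of a TS-PPI network
#' @param net a `tsppi_network`.
#' @return data frame with columns `gene_a`, `gene_b`, `weight`, `label`,
#'   `coverage`.
#' @export
tsppi_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), label = character(),
                      coverage = numeric()))
  el <- igraph::as_edgelist(g)
  data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
             weight = igraph::E(g)$weight,
             label = if (is.null(igraph::E(g)$label)) NA_character_
                     else igraph::E(g)$label,
             coverage = if (is.null(igraph::E(g)$coverage)) NA_real_
                        else igraph::E(g)$coverage,
             stringsAsFactors = FALSE)
}

#' Named node-weight vector of a TS-PPI network
#' @param net a `tsppi_network`.
#' @return named numeric vector of expression scores.
#' @export
node_weights <- function(net) {
  setNames(igraph::V(net$graph)$weight, igraph::V(net$graph)$name)
}

#' @export
print.tsppi_network <- function(x, ...) {
  cat(sprintf("TS-PPI network '%s': %d nodes, %d edges",
              x$name, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (length(x$conditions) > 0)
    cat(" [", paste(x$conditions, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# Adjacency as a named list: gene -> character vector of neighbour genes.
tsppi_adjacency <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) return(list())
  al <- igraph::as_adj_list(g, mode = "all")
  out <- lapply(al, function(v) igraph::V(g)$name[as.integer(v)])
  names(out) <- igraph::V(g)$name
  out
}
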