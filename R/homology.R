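#' Label-identity homology scheme
#'
#' The default scheme for deciding which nodes of different networks may be
#' aligned: two nodes are homologs iff they carry the same gene symbol, with
#' score 1.  Use [read_homology_file()] for an explicit scoring scheme.
#'
#' @return an object of class `homology_map`.
#' @export
homology_by_label <- function() {
  structure(list(type = "label"), class = "homology_map")
}

homology_key <- function(net_a, node_a, net_b, node_b) {
  swap <- net_b < net_a | (net_b == net_a & node_b < node_a)
  ka <- ifelse(swap, net_b, net_a); na_ <- ifelse(swap, node_b, node_a)
  kb <- ifelse(swap, net_a, net_b); nb_ <- ifelse(swap, node_a, node_b)
  paste(ka, na_, kb, nb_, sep = "\r")
}

#' Homology score of a node pair
#'
#' @param homology a `homology_map` (from [homology_by_label()] or
#'   [read_homology_file()]).
#' @param net_a,node_a network name and gene symbol of the first node.
#' @param net_b,node_b network name and gene symbol of the second node.
#' @return non-negative score; 0 means the nodes may not be aligned.
#' @export
homology_pair_score <- function(homology, net_a, node_a, net_b, node_b) {
  if (homology$type == "label")
    return(as.numeric(node_a == node_b))
  s <- unname(homology$scores[homology_key(net_a, node_a, net_b, node_b)])
  ifelse(is.na(s), 0, s)
}

# Mean pairwise homology score of a full column (members named by network);
# 0 if any pair is non-homologous.
column_homology_score <- function(homology, members) {
  nets <- names(members)
  n <- length(members)
  if (homology$type == "label") {
    return(if (length(unique(members)) == 1L) 1 else 0)
  }
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- homology_pair_score(homology, nets[i], members[i],
                               nets[j], members[j])
      if (s <= 0) return(0)
      tot <- tot + s
    }
  }
  tot / (n * (n - 1) / 2)
}
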