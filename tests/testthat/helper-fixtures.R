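# Shared fixture builders.  Everything is generated in code; no data files.

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# A small TS-PPI network from a compact edge description.
# edges: data.frame(gene_a, gene_b, weight); weights: named node weights.
make_net <- function(weights, edges, name = "net",
                     conditions = name) {
  tsppi_network(
    nodes = data.frame(gene = names(weights), weight = unname(weights)),
    edges = edges, name = name, conditions = conditions)
}

# N networks sharing one backbone, with per-network node weight matrix
# (genes x networks).
make_family <- function(wmat, edges) {
  nets <- lapply(seq_len(ncol(wmat)), function(i) {
    make_net(setNames(wmat[, i], rownames(wmat)), edges,
             name = paste0("net", i))
  })
  names(nets) <- paste0("net", seq_len(ncol(wmat)))
  nets
}

# Independent quantile-normalization oracle: sort each column, average
# across columns by rank, then map each value back through its (tie-
# averaged) rank by linear interpolation between adjacent rank means.
qn_oracle <- function(m) {
  rank_means <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- stats::approx(seq_along(rank_means), rank_means,
                              xout = r)$y
  }
  out
}

# Random small global network + expression table for builder tests.
random_build_inputs <- function(seed) {
  set.seed(seed)
  genes <- paste0("G", 1:12)
  pairs <- t(utils::combn(genes, 2))
  n_ds <- sample(2:4, 1)
  datasets <- lapply(seq_len(n_ds), function(d) {
    sel <- pairs[sample.int(nrow(pairs), sample(8:20, 1)), , drop = FALSE]
    data.frame(gene_a = sel[, 1], gene_b = sel[, 2],
               weight = round(runif(nrow(sel)), 3),
               stringsAsFactors = FALSE)
  })
  names(datasets) <- paste0("ppi", seq_len(n_ds))
  gn <- merge_interaction_datasets(datasets)
  tissues <- c("liver", "kidney")
  mats <- list(expr1 = matrix(round(runif(24, 0.5, 16), 3), nrow = 12,
                              dimnames = list(genes, tissues)))
  mats$expr1[runif(24) < 0.2] <- NA
  expr <- build_expression_table(mats)
  list(global = gn, expr = expr, genes = genes)
}

# Brute-force TS-PPI filter oracle: direct per-edge scan, independent of
# build_tsppi().
brute_force_tsppi <- function(global, expr, filter, condition) {
  sc <- expr_scores(if (is.null(filter$expression_datasets)) expr
                    else restrict_to_datasets(expr,
                                              filter$expression_datasets))
  sc <- sc[sc$condition == condition, , drop = FALSE]
  expressed <- setNames(sc$score, sc$gene)
  if (!is.null(filter$min_expression))
    expressed <- expressed[expressed >= filter$min_expression]
  if (!is.null(filter$gene_list))
    expressed <- expressed[names(expressed) %in% filter$gene_list]
  keep <- list()
  for (i in seq_len(nrow(global$edges))) {
    e <- global$edges[i, ]
    if (!is.null(filter$min_edge_weight) &&
        e$avg_weight < filter$min_edge_weight) next
    if (!is.null(filter$min_coverage) &&
        e$coverage < filter$min_coverage) next
    if (!is.null(filter$interaction_datasets) &&
        !any(names(global$weights[[i]]) %in% filter$interaction_datasets))
      next
    if (!(e$gene_a %in% names(expressed)) ||
        !(e$gene_b %in% names(expressed))) next
    keep[[length(keep) + 1L]] <- e
  }
  if (length(keep) == 0)
    return(list(nodes = character(0),
                edges = data.frame(gene_a = character(),
                                   gene_b = character())))
  ed <- do.call(rbind, keep)
  list(nodes = sort(unique(c(ed$gene_a, ed$gene_b))),
       edges = ed[order(ed$gene_a, ed$gene_b),
                  c("gene_a", "gene_b", "avg_weight", "coverage")])
}
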