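# Ground-truthed synthetic inputs: families of node-weighted networks with
# a planted conserved connected subnetwork whose columns have a guaranteed
# pairwise expression divergence against a low-divergence background, plus
# small seeded fixtures for the integration stage.

#' Specification of a synthetic network family
#'
#' The defaults mirror a four-condition comparison (for instance normal
#' tissue against three tumor grades) over a scale-free interaction
#' backbone: 4 networks of 300 genes with a planted connected subnetwork of
#' 8 genes whose columns are guaranteed a pairwise log2 divergence of at
#' least `planted_fold = 2`, against background columns whose divergence
#' never exceeds `background_fold_max = 0.3`.
#'
#' @param n_networks number of networks (>= 2).
#' @param n_genes genes per network.
#' @param backbone_model `"scale-free"` (preferential attachment, the
#'   degree distribution observed in integrated interaction networks) or
#'   `"erdos-renyi"`.
#' @param attachment_or_p edges added per vertex (scale-free) or edge
#'   probability (Erdős–Rényi).
#' @param planted_size size of the planted connected subnetwork.
#' @param planted_fold guaranteed minimum MaxLogFold of planted columns
#'   (log2 units).
#' @param background_fold_max maximum MaxLogFold of background columns;
#'   must not exceed `planted_fold`.
#' @param base_expression central expression score (default 8, the middle
#'   of a typical log2 expression scale).
#' @param noise_sd Gaussian noise, in log2 units, perturbing node weights
#'   within the guard bands (so fold guarantees are deterministic).
#' @param edge_weight_range interval in \[0, 1\] for interaction weights.
#' @param seed optional RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_networks = 4, n_genes = 300,
                           backbone_model = c("scale-free", "erdos-renyi"),
                           attachment_or_p = 2, planted_size = 8,
                           planted_fold = 2, background_fold_max = 0.3,
                           base_expression = 8, noise_sd = 0.05,
                           edge_weight_range = c(0.4, 1), seed = NULL) {
  backbone_model <- match.arg(backbone_model)
  stopifnot(n_networks >= 2, n_genes >= 2,
            planted_size >= 1, planted_size <= n_genes,
            planted_fold >= 0, background_fold_max >= 0,
            base_expression > 0, noise_sd >= 0,
            length(edge_weight_range) == 2,
            edge_weight_range[1] >= 0, edge_weight_range[2] <= 1,
            edge_weight_range[1] <= edge_weight_range[2])
  if (background_fold_max > planted_fold)
    stop("background_fold_max must not exceed planted_fold")
  structure(list(n_networks = as.integer(n_networks),
                 n_genes = as.integer(n_genes),
                 backbone_model = backbone_model,
                 attachment_or_p = attachment_or_p,
                 planted_size = as.integer(planted_size),
                 planted_fold = planted_fold,
                 background_fold_max = background_fold_max,
                 base_expression = base_expression,
                 noise_sd = noise_sd,
                 edge_weight_range = edge_weight_range,
                 seed = seed),
            class = "synthetic_spec")
}

# random connected induced subgraph grown from a random start vertex
grow_connected_subset <- function(adj, size) {
  start <- sample_one(names(adj))
  current <- start
  frontier <- setdiff(adj[[start]], current)
  while (length(current) < size) {
    if (length(frontier) == 0) return(NULL)
    nxt <- sample_one(frontier)
    current <- c(current, nxt)
    frontier <- setdiff(unique(c(frontier, adj[[nxt]])), current)
  }
  current
}

#' Generate a synthetic network family with a planted subnetwork
#'
#' One interaction backbone is generated and shared by all networks (so
#' label-identity homology holds); a connected subgraph of `planted_size`
#' genes is planted.  In log2 space, each planted gene receives one
#' network at `+planted_fold/2` (plus outward noise), one at
#' `-planted_fold/2` (minus outward noise) and the remaining networks
#' inside the band, so its column MaxLogFold is at least `planted_fold`;
#' background genes stay inside `±background_fold_max/2`, so their column
#' MaxLogFold never exceeds `background_fold_max`.  Edge weights are drawn
#' uniformly from `edge_weight_range`, independently per network.
#'
#' @param spec a [synthetic_spec].
#' @return an object of class `synthetic_instance`: a named list
#'   `networks` of [tsppi_network]s and a `truth` list with the planted
#'   `genes` and `edges`.
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_genes
  labels <- sprintf("G%04d", seq_len(n))
  g <- if (spec$backbone_model == "scale-free") {
    igraph::sample_pa(n, m = spec$attachment_or_p, directed = FALSE)
  } else {
    igraph::sample_gnp(n, p = spec$attachment_or_p)
  }
  igraph::V(g)$name <- labels
  comp <- igraph::components(g)
  if (max(comp$csize) < spec$planted_size)
    stop("planted subnetwork of size ", spec$planted_size,
         " does not fit in the largest connected component (size ",
         max(comp$csize), ")")
  big <- labels[comp$membership == which.max(comp$csize)]
  adj_all <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj_all, function(v) labels[as.integer(v)])
  names(adj) <- labels
  planted <- NULL
  while (is.null(planted)) {
    planted <- grow_connected_subset(adj[big], spec$planted_size)
  }

  nets <- paste0("net", seq_len(spec$n_networks))
  half <- spec$planted_fold / 2
  bg_half <- spec$background_fold_max / 2
  expo <- matrix(NA_real_, nrow = n, ncol = spec$n_networks,
                 dimnames = list(labels, nets))
  is_planted <- labels %in% planted
  n_bg <- sum(!is_planted)
  if (n_bg > 0) {
    u <- runif(n_bg * spec$n_networks, -bg_half, bg_half) +
      rnorm(n_bg * spec$n_networks, sd = spec$noise_sd)
    expo[!is_planted, ] <- pmin(pmax(u, -bg_half), bg_half)
  }
  for (gn in planted) {
    extremes <- sample.int(spec$n_networks, 2L)
    e <- runif(spec$n_networks, -half, half) +
      rnorm(spec$n_networks, sd = spec$noise_sd)
    e <- pmin(pmax(e, -half), half)
    e[extremes[1L]] <- half + abs(rnorm(1, sd = spec$noise_sd))
    e[extremes[2L]] <- -half - abs(rnorm(1, sd = spec$noise_sd))
    expo[gn, ] <- e
  }
  weights <- spec$base_expression * 2^expo

  el <- igraph::as_edgelist(g)
  networks <- list()
  for (i in seq_len(spec$n_networks)) {
    ew <- runif(nrow(el), spec$edge_weight_range[1L],
                spec$edge_weight_range[2L])
    networks[[nets[i]]] <- tsppi_network(
      nodes = data.frame(gene = labels, weight = weights[, i]),
      edges = data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                         weight = ew, label = nets[i]),
      name = nets[i], conditions = nets[i])
  }
  planted_edges <- el[el[, 1L] %in% planted & el[, 2L] %in% planted, ,
                      drop = FALSE]
  structure(list(
    networks = networks,
    truth = list(genes = sort(planted),
                 edges = data.frame(gene_a = pmin(planted_edges[, 1L],
                                                  planted_edges[, 2L]),
                                    gene_b = pmax(planted_edges[, 1L],
                                                  planted_edges[, 2L]),
                                    stringsAsFactors = FALSE)),
    spec = spec), class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "Synthetic family: %d networks, %d genes, planted subnetwork of %d\n",
    length(x$networks), x$spec$n_genes, length(x$truth$genes)))
  invisible(x)
}

#' Score recovery of the planted subnetwork
#'
#' Standard set-overlap metrics between the nodes of the top-ranked
#' alignment and the planted nodes, computed per network and averaged.
#'
#' @param result list of [alignment]s as returned by [align_networks()].
#' @param truth the `truth` element of a `synthetic_instance` (or any list
#'   with a `genes` component).
#' @return list with `precision`, `recall` and `f1` (all 0 for an empty
#'   result).
#' @export
score_recovery <- function(result, truth) {
  if (length(result) == 0)
    return(list(precision = 0, recall = 0, f1 = 0))
  top <- result[[1L]]
  planted <- truth$genes
  per_net <- vapply(seq_along(top$networks), function(i) {
    pred <- unique(top$columns[, i])
    tp <- length(intersect(pred, planted))
    c(tp / length(pred), tp / length(planted))
  }, numeric(2))
  precision <- mean(per_net[1L, ])
  recall <- mean(per_net[2L, ])
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Seeded fixture for the integration stage, with embedded expectations
#'
#' Generates small named interaction datasets (mixing weighted and
#' unweighted) and expression matrices with missing cells, together with
#' the expected merged network and expression scores computed by a direct
#' per-edge / per-pair scan that is independent of
#' [merge_interaction_datasets()] and [build_expression_table()].
#'
#' @param seed RNG seed.
#' @return list with `interactions`, `expressions`, `expected_network`
#'   (data frame `gene_a`, `gene_b`, `avg_weight`, `coverage`) and
#'   `expected_scores` (data frame `gene`, `condition`, `score`).
#' @export
make_integration_fixture <- function(seed = 1) {
  set.seed(seed)
  genes <- paste0("G", 1:10)
  tissues <- paste0("tissue", seq_len(sample(2:5, 1)))
  n_ds <- sample(2:6, 1)
  weighted <- sample(c(TRUE, FALSE), n_ds, replace = TRUE)
  weighted[1] <- TRUE; if (n_ds > 1) weighted[2] <- FALSE
  pairs <- t(utils::combn(genes, 2))
  interactions <- list()
  for (d in seq_len(n_ds)) {
    m <- sample(3:8, 1)
    sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    interactions[[paste0("ppi", d)]] <- data.frame(
      gene_a = sel[, 1L], gene_b = sel[, 2L],
      weight = if (weighted[d]) round(runif(m, 0.1, 1), 3)
               else rep(NA_real_, m),
      stringsAsFactors = FALSE)
  }
  n_expr <- sample(1:3, 1)
  expressions <- list()
  for (d in seq_len(n_expr)) {
    m <- matrix(round(runif(length(genes) * length(tissues), 1, 16), 3),
                nrow = length(genes),
                dimnames = list(genes, tissues))
    m[runif(length(m)) < 0.3] <- NA_real_
    expressions[[paste0("expr", d)]] <- m
  }

  # --- embedded brute-force oracle: direct scans, no package internals ---
  keys <- unique(unlist(lapply(interactions, function(d)
    paste(pmin(d$gene_a, d$gene_b), pmax(d$gene_a, d$gene_b)))))
  keys <- sort(keys)
  expected_network <- do.call(rbind, lapply(keys, function(k) {
    ab <- strsplit(k, " ")[[1L]]
    contribs <- c()
    for (d in interactions) {
      hit <- (pmin(d$gene_a, d$gene_b) == ab[1L]) &
        (pmax(d$gene_a, d$gene_b) == ab[2L])
      if (any(hit)) {
        w <- d$weight[hit]
        contribs <- c(contribs,
                      if (all(is.na(w))) 1 else mean(w, na.rm = TRUE))
      }
    }
    data.frame(gene_a = ab[1L], gene_b = ab[2L],
               avg_weight = mean(contribs),
               coverage = length(contribs) / length(interactions),
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (gn in genes) {
    for (tt in tissues) {
      vals <- c()
      for (m in expressions) {
        v <- m[gn, tt]
        if (!is.na(v)) vals <- c(vals, v)
      }
      if (length(vals) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gn, condition = tt, score = mean(vals),
          stringsAsFactors = FALSE)
    }
  }
  list(interactions = interactions, expressions = expressions,
       expected_network = expected_network,
       expected_scores = do.call(rbind, rows))
}
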