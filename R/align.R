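# Stochastic multiple differential local alignment of node-weighted TS-PPI
# networks: Gibbs-sampled seeds, divergence-driven extension, removal of the
# least divergent column, ISC ranking and overlap pruning.

#' Alignment parameters
#'
#' @param sigma minimum degree of seed candidate nodes (non-negative
#'   integer, default 1).
#' @param alpha probability threshold in (0, 1) governing the Gibbs
#'   sampling iteration budget (default 0.05); see
#'   [gibbs_iteration_budget()].
#' @param overlap_threshold maximum average overlap between reported
#'   alignments, in \[0, 1\] (default 0.5).
#' @param refine_iterations iterations of the refinement phase (extend
#'   steps followed by a removal step; default 10).
#' @param min_alignment_size alignments smaller than this are not reported
#'   (default 3).
#' @param max_logfold_threshold minimum expression log-fold divergence
#'   driving the extension process (default 0.6; for log-transformed
#'   expression data values in 0.2--1 are typical).
#' @param attempts number of independent seeded runs (default 50).
#' @param seed optional RNG seed recorded for reproducibility; identical
#'   seeds give identical output.
#' @param epsilon guard added to MaxLogFold inside sampling probabilities
#'   so equal-expression columns remain sampleable (default 0.01).  Raw
#'   MaxLogFold (no guard) is used for thresholding, removal and
#'   reporting.
#' @param epsilon_expr expression values at or below this are clamped
#'   before fold computation (default 1e-6).
#' @return an object of class `alignment_parameters`.
#' @export
alignment_parameters <- function(sigma = 1, alpha = 0.05,
                                 overlap_threshold = 0.5,
                                 refine_iterations = 10,
                                 min_alignment_size = 3,
                                 max_logfold_threshold = 0.6,
                                 attempts = 50, seed = NULL,
                                 epsilon = 0.01, epsilon_expr = 1e-6) {
  stopifnot(sigma >= 0, sigma == round(sigma),
            alpha > 0, alpha < 1,
            overlap_threshold >= 0, overlap_threshold <= 1,
            refine_iterations >= 1,
            min_alignment_size >= 1,
            max_logfold_threshold >= 0,
            attempts >= 1, epsilon > 0, epsilon_expr > 0)
  structure(list(sigma = as.integer(sigma), alpha = alpha,
                 overlap_threshold = overlap_threshold,
                 refine_iterations = as.integer(refine_iterations),
                 min_alignment_size = as.integer(min_alignment_size),
                 max_logfold_threshold = max_logfold_threshold,
                 attempts = as.integer(attempts), seed = seed,
                 epsilon = epsilon, epsilon_expr = epsilon_expr),
            class = "alignment_parameters")
}

#' Construct an alignment object
#'
#' An alignment is an ordered set of columns; each column maps one node per
#' network (no node appears in two columns) and carries its MaxLogFold.
#'
#' @param columns character matrix, one row per aligned column, one column
#'   per network (colnames = network names).
#' @param max_logfold numeric vector of per-column MaxLogFold values.
#' @param isc index of structural conservation, if computed.
#' @return an object of class `alignment`.
#' @export
alignment <- function(columns, max_logfold, isc = NA_real_) {
  columns <- as.matrix(columns)
  if (is.null(colnames(columns)))
    stop("alignment columns need network names as colnames")
  if (length(max_logfold) != nrow(columns))
    stop("one MaxLogFold value per aligned column is required")
  structure(list(columns = columns,
                 max_logfold = as.numeric(max_logfold),
                 avg_max_logfold = mean(as.numeric(max_logfold)),
                 isc = isc,
                 networks = colnames(columns)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf(
    "Local alignment: size %d over %d networks, avg MaxLogFold %.4g, ISC %s\n",
    nrow(x$columns), ncol(x$columns), x$avg_max_logfold,
    ifelse(is.na(x$isc), "not computed", sprintf("%.4g", x$isc))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Family index: everything the sampler needs, computed once per family.

family_index <- function(networks, homology, params) {
  if (length(networks) < 2)
    stop("at least two networks are required")
  if (is.null(names(networks)) || anyDuplicated(names(networks)))
    stop("networks must be a uniquely named list")
  if (!all(vapply(networks, inherits, logical(1), "tsppi_network")))
    stop("all inputs must be tsppi_network objects")
  if (any(vapply(networks, function(x) igraph::vcount(x$graph),
                 numeric(1)) == 0))
    stop("at least two non-empty networks are required")
  if (homology$type == "file" && length(homology$scores) == 0)
    stop("homology map is empty")
  n <- length(networks)
  nets <- names(networks)
  adj <- lapply(networks, tsppi_adjacency)
  wts <- lapply(networks, node_weights)
  deg <- lapply(adj, lengths)
  idx <- list(n = n, nets = nets, adj = adj, wts = wts, deg = deg,
              homology = homology, params = params,
              label_mode = homology$type == "label")
  if (idx$label_mode) {
    common <- Reduce(intersect, lapply(wts, names))
    idx$common <- common
    if (length(common) > 0) {
      W <- vapply(wts, function(w) unname(w[common]), numeric(length(common)))
      W <- matrix(W, nrow = length(common),
                  dimnames = list(common, nets))
      W <- pmax(W, params$epsilon_expr)
      idx$fold <- setNames(
        log2(apply(W, 1, max) / apply(W, 1, min)), common)
    } else {
      idx$fold <- setNames(numeric(0), character(0))
    }
    # seed candidates: common genes with degree >= sigma in every network
    ok <- vapply(common, function(g) {
      all(vapply(deg, function(d) d[[g]] >= params$sigma, logical(1)))
    }, logical(1))
    idx$seed_pool <- common[ok]
  } else {
    # per ordered network pair: node -> named score vector of homologs
    parts <- strsplit(names(homology$scores), "\r", fixed = TRUE)
    hd <- data.frame(net_a = vapply(parts, `[`, character(1), 1L),
                     node_a = vapply(parts, `[`, character(1), 2L),
                     net_b = vapply(parts, `[`, character(1), 3L),
                     node_b = vapply(parts, `[`, character(1), 4L),
                     score = unname(homology$scores),
                     stringsAsFactors = FALSE)
    hd2 <- rbind(hd, data.frame(net_a = hd$net_b, node_a = hd$node_b,
                                net_b = hd$net_a, node_b = hd$node_a,
                                score = hd$score))
    hom <- list()
    for (i in nets) {
      hom[[i]] <- list()
      for (j in nets) {
        if (i == j) next
        sel <- hd2$net_a == i & hd2$net_b == j &
          hd2$node_a %in% names(wts[[i]]) & hd2$node_b %in% names(wts[[j]])
        hom[[i]][[j]] <- split(
          setNames(hd2$score[sel], hd2$node_b[sel]), hd2$node_a[sel])
      }
    }
    idx$hom <- hom
    idx$seed_sets <- lapply(nets, function(i) {
      nodes <- names(wts[[i]])[deg[[i]] >= params$sigma]
      keep <- vapply(nodes, function(x) {
        all(vapply(setdiff(nets, i), function(j) {
          length(hom[[i]][[j]][[x]]) > 0
        }, logical(1)))
      }, logical(1))
      nodes[keep]
    })
    names(idx$seed_sets) <- nets
  }
  idx
}

column_fold <- function(idx, members) {
  w <- pmax(vapply(seq_len(idx$n),
                   function(i) unname(idx$wts[[i]][members[i]]),
                   numeric(1)),
            idx$params$epsilon_expr)
  log2(max(w) / min(w))
}

# 1 + number of aligned columns whose interaction with the candidate is
# conserved in every network.  Vectorized over candidate genes (label mode).
topology_counts_label <- function(idx, cols, cands) {
  topo <- setNames(rep(1, length(cands)), cands)
  if (is.null(cols) || nrow(cols) == 0) return(topo)
  for (r in seq_len(nrow(cols))) {
    nb <- Reduce(intersect,
                 lapply(seq_len(idx$n), function(i) idx$adj[[i]][[cols[r, i]]]))
    hit <- cands %in% nb
    topo[hit] <- topo[hit] + 1
  }
  topo
}

topology_count_column <- function(idx, cols, members) {
  if (is.null(cols) || nrow(cols) == 0) return(1)
  1 + sum(vapply(seq_len(nrow(cols)), function(r) {
    all(vapply(seq_len(idx$n), function(i) {
      members[i] %in% idx$adj[[i]][[cols[r, i]]]
    }, logical(1)))
  }, logical(1)))
}

#' Sampling similarity of a candidate alignment column
#'
#' The probability weight of a candidate column in the Gibbs sampler:
#' `(epsilon + MaxLogFold(column)) * homology_score * topology_score`.
#' The homology score is the mean pairwise homology of the members (1
#' under label identity); the topology score is 1 plus the number of
#' already-aligned columns whose interaction with the candidate is
#' conserved in every network, so candidates adding conserved edges are
#' favoured while seeds and loosely attached candidates keep a positive
#' weight.
#'
#' @param members named character vector: one node per network (names =
#'   network names).
#' @param networks named list of `tsppi_network` objects.
#' @param homology a `homology_map`.
#' @param current_alignment optional [alignment] the candidate would
#'   extend.
#' @param epsilon divergence guard (default 0.01).
#' @param epsilon_expr expression clamping guard (default 1e-6).
#' @return strictly positive similarity.
#' @export
node_similarity <- function(members, networks, homology,
                            current_alignment = NULL, epsilon = 0.01,
                            epsilon_expr = 1e-6) {
  members <- members[names(networks)]
  if (any(is.na(members)))
    stop("candidate column needs one member per network")
  hs <- column_homology_score(homology, members)
  if (hs <= 0)
    stop("candidate column members are not mutual homologs")
  idx <- family_index(networks, homology,
                      alignment_parameters(epsilon = epsilon,
                                           epsilon_expr = epsilon_expr))
  cols <- if (is.null(current_alignment)) NULL
          else current_alignment$columns
  fold <- column_fold(idx, unname(members))
  (epsilon + fold) * hs * topology_count_column(idx, cols, unname(members))
}

# ---------------------------------------------------------------------------
# Bootstrap phase

sample_one <- function(x, prob = NULL) {
  x[sample.int(length(x), 1L, prob = prob)]
}

initial_column <- function(idx) {
  if (idx$label_mode) {
    if (length(idx$seed_pool) == 0)
      stop("no seed candidates: no gene shared by all networks has ",
           "degree >= sigma everywhere")
    g <- sample_one(idx$seed_pool)
    return(setNames(rep(g, idx$n), idx$nets))
  }
  if (any(lengths(idx$seed_sets) == 0))
    stop("no seed candidates in network '",
         idx$nets[lengths(idx$seed_sets) == 0][1L], "'")
  for (try in seq_len(100L)) {
    members <- setNames(rep(NA_character_, idx$n), idx$nets)
    members[1L] <- sample_one(idx$seed_sets[[1L]])
    ok <- TRUE
    for (j in seq(2L, idx$n)) {
      cands <- idx$seed_sets[[j]]
      for (i in seq_len(j - 1L)) {
        hom_ij <- idx$hom[[idx$nets[j]]][[idx$nets[i]]]
        cands <- cands[vapply(cands, function(x) {
          members[i] %in% names(hom_ij[[x]])
        }, logical(1))]
      }
      if (length(cands) == 0) { ok <- FALSE; break }
      members[j] <- sample_one(cands)
    }
    if (ok) return(members)
  }
  stop("no seed candidates: could not assemble a mutually homologous column")
}

# candidates for replacing the member of network i, given the other members
replacement_candidates <- function(idx, members, i, pool) {
  if (idx$label_mode) {
    g <- members[-i][1L]
    return(intersect(g, pool))
  }
  cands <- pool
  for (j in seq_len(idx$n)[-i]) {
    hom_ij <- idx$hom[[idx$nets[i]]][[idx$nets[j]]]
    cands <- cands[vapply(cands, function(x) {
      members[j] %in% names(hom_ij[[x]])
    }, logical(1))]
  }
  cands
}

column_similarity <- function(idx, members) {
  hs <- column_homology_score(idx$homology, setNames(members, idx$nets))
  (idx$params$epsilon + column_fold(idx, members)) * hs
}

run_gibbs_seed <- function(idx, params) {
  members <- initial_column(idx)
  k <- gibbs_iteration_budget(idx$n, params$alpha)
  unchanged <- 0L
  while (unchanged < k) {
    i <- sample.int(idx$n, 1L)
    pool <- if (idx$label_mode) idx$seed_pool else idx$seed_sets[[i]]
    cands <- unique(c(members[i], replacement_candidates(idx, members, i, pool)))
    sims <- vapply(cands, function(x) {
      m <- members; m[i] <- x
      column_similarity(idx, unname(m))
    }, numeric(1))
    pick <- sample_one(cands, prob = sims)
    if (pick == members[[i]]) {
      unchanged <- unchanged + 1L
    } else {
      members[i] <- pick
      unchanged <- 0L
    }
  }
  members
}

#' Sample a seed column by Gibbs sampling
#'
#' Starting from a random mutually homologous column of nodes with degree
#' at least `sigma`, the sampler repeatedly replaces the member of one
#' randomly chosen network with a same-network candidate drawn
#' proportionally to [node_similarity()], and stops once the column is
#' unchanged for [gibbs_iteration_budget()] consecutive iterations.
#'
#' @param networks named list of `tsppi_network` objects (>= 2).
#' @param homology a `homology_map`.
#' @param params an [alignment_parameters] object; `params$seed`, when
#'   set, makes the draw reproducible.
#' @return a single-column [alignment].
#' @export
bootstrap_seed <- function(networks, homology = homology_by_label(),
                           params = alignment_parameters()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- family_index(networks, homology, params)
  members <- run_gibbs_seed(idx, params)
  cols <- matrix(members, nrow = 1, dimnames = list(NULL, idx$nets))
  alignment(cols, column_fold(idx, members))
}

# ---------------------------------------------------------------------------
# Extension and removal

enumerate_extension_columns <- function(idx, cols, cap = 2000L) {
  frontiers <- lapply(seq_len(idx$n), function(i) {
    used <- cols[, i]
    setdiff(unique(unlist(idx$adj[[i]][used], use.names = FALSE)), used)
  })
  if (any(lengths(frontiers) == 0)) return(NULL)
  if (idx$label_mode) {
    cands <- Reduce(intersect, frontiers)
    if (length(cands) == 0) return(NULL)
    return(lapply(cands, function(g) setNames(rep(g, idx$n), idx$nets)))
  }
  partial <- lapply(frontiers[[1L]], function(x) x)
  for (j in seq(2L, idx$n)) {
    nxt <- list()
    for (p in partial) {
      for (x in frontiers[[j]]) {
        ok <- all(vapply(seq_len(j - 1L), function(i) {
          p[i] %in% names(idx$hom[[idx$nets[j]]][[idx$nets[i]]][[x]])
        }, logical(1)))
        if (ok) nxt[[length(nxt) + 1L]] <- c(p, x)
        if (length(nxt) > cap) break
      }
      if (length(nxt) > cap) break
    }
    if (length(nxt) == 0) return(NULL)
    partial <- nxt
  }
  lapply(partial, function(m) setNames(m, idx$nets))
}

extend_once <- function(idx, al, params) {
  cols <- al$columns
  if (idx$label_mode) {
    frontiers <- lapply(seq_len(idx$n), function(i) {
      used <- cols[, i]
      setdiff(unique(unlist(idx$adj[[i]][used], use.names = FALSE)), used)
    })
    cands <- Reduce(intersect, frontiers)
    # divergence requirement: only columns sustaining the threshold are
    # extension candidates, so the alignment average never drifts below it
    cands <- cands[unname(idx$fold[cands]) >= params$max_logfold_threshold]
    if (length(cands) == 0) return(NULL)
    sims <- (params$epsilon + unname(idx$fold[cands])) *
      unname(topology_counts_label(idx, cols, cands))
    pick <- sample_one(cands, prob = sims)
    members <- setNames(rep(pick, idx$n), idx$nets)
  } else {
    columns <- enumerate_extension_columns(idx, cols)
    if (is.null(columns)) return(NULL)
    folds <- vapply(columns, function(m) column_fold(idx, unname(m)),
                    numeric(1))
    keep <- folds >= params$max_logfold_threshold
    if (!any(keep)) return(NULL)
    columns <- columns[keep]
    sims <- vapply(columns, function(m) {
      column_similarity(idx, unname(m)) *
        topology_count_column(idx, cols, unname(m))
    }, numeric(1))
    members <- columns[[sample.int(length(columns), 1L, prob = sims)]]
  }
  list(members = members, fold = column_fold(idx, unname(members)))
}

extend_engine <- function(idx, al, params) {
  repeat {
    cand <- extend_once(idx, al, params)
    if (is.null(cand)) break
    al <- alignment(rbind(al$columns, cand$members),
                    c(al$max_logfold, cand$fold), al$isc)
  }
  al
}

#' Extend an alignment with divergent adjacent columns
#'
#' Repeatedly samples a new column -- one unused node per network, adjacent
#' to that network's aligned subgraph, mutually homologous, and with
#' MaxLogFold at least `max_logfold_threshold` -- with probability
#' proportional to [node_similarity()].  The alignment is thus extended as
#' long as the divergence requirement can be sustained, and stops when no
#' admissible candidate column remains in some network.  Per-network
#' connectivity is preserved by construction.
#'
#' @inheritParams bootstrap_seed
#' @param alignment a non-empty [alignment].
#' @return the extended [alignment].
#' @export
extend_alignment <- function(alignment, networks,
                             homology = homology_by_label(),
                             params = alignment_parameters()) {
  if (nrow(alignment$columns) == 0) stop("cannot extend an empty alignment")
  idx <- family_index(networks, homology, params)
  extend_engine(idx, alignment, params)
}

connected_set <- function(members, adj) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1L]
  frontier <- members[1L]
  while (length(frontier) > 0) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(intersect(nb, members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

remove_worst_engine <- function(idx, al) {
  w <- nrow(al$columns)
  if (w < 2) return(al)
  tie_key <- apply(al$columns, 1, paste, collapse = "\r")
  ord <- order(al$max_logfold, tie_key)
  for (r in ord) {
    rest <- al$columns[-r, , drop = FALSE]
    ok <- all(vapply(seq_len(idx$n), function(i) {
      connected_set(rest[, i], idx$adj[[i]])
    }, logical(1)))
    if (ok)
      return(alignment(rest, al$max_logfold[-r], al$isc))
  }
  al
}

#' Remove the least divergent column of an alignment
#'
#' Deletes the column with minimal MaxLogFold, unless its removal would
#' disconnect a per-network subgraph, in which case the least divergent
#' *removable* column is deleted.  Ties are broken deterministically
#' (lexicographically on the member labels).  Alignments of size < 2 are
#' returned unchanged.
#'
#' @param alignment an [alignment].
#' @param networks named list of `tsppi_network` objects.
#' @return the reduced [alignment].
#' @export
remove_worst <- function(alignment, networks) {
  idx <- list(n = length(networks),
              adj = lapply(networks, tsppi_adjacency))
  remove_worst_engine(idx, alignment)
}

# ---------------------------------------------------------------------------
# Post-processing

#' Rank alignments
#'
#' Deterministic total order: descending ISC, ties by descending average
#' MaxLogFold, then by descending size, then lexicographically on the
#' member labels.
#'
#' @param alignments list of [alignment] objects with ISC computed.
#' @return the reordered list.
#' @export
rank_alignments <- function(alignments) {
  if (length(alignments) == 0) return(alignments)
  iscs <- vapply(alignments, function(a) a$isc, numeric(1))
  avgs <- vapply(alignments, function(a) a$avg_max_logfold, numeric(1))
  sizes <- vapply(alignments, function(a) nrow(a$columns), numeric(1))
  keys <- vapply(alignments, function(a) {
    paste(sort(as.vector(a$columns)), collapse = ",")
  }, character(1))
  alignments[order(-iscs, -avgs, -sizes, keys)]
}

alignment_overlap <- function(a, b) {
  mean(vapply(seq_along(a$networks), function(i) {
    length(intersect(a$columns[, i], b$columns[, i])) /
      min(nrow(a$columns), nrow(b$columns))
  }, numeric(1)))
}

#' Remove highly overlapping alignments
#'
#' Greedy sweep in rank order: an alignment is kept iff its average
#' per-network node overlap with every already-kept alignment is at most
#' `overlap_threshold` (overlap of two alignments: mean over networks of
#' the intersection size divided by the smaller alignment size).
#'
#' @param alignments ranked list of [alignment] objects.
#' @param overlap_threshold maximum tolerated overlap in \[0, 1\].
#' @return the filtered list.
#' @export
prune_overlaps <- function(alignments, overlap_threshold = 0.5) {
  kept <- list()
  for (al in alignments) {
    over <- vapply(kept, alignment_overlap, numeric(1), a = al)
    if (all(over <= overlap_threshold))
      kept[[length(kept) + 1L]] <- al
  }
  kept
}

# ---------------------------------------------------------------------------
# Full pipeline

#' Multiple differential local alignment of TS-PPI networks
#'
#' Runs `attempts` independent seeded runs.  Each run draws a seed column
#' by Gibbs sampling ([bootstrap_seed()]), then alternates extension and
#' removal for `refine_iterations` rounds and performs a final extension.
#' Alignments smaller than `min_alignment_size` or with average MaxLogFold
#' below `max_logfold_threshold` are discarded; survivors are scored
#' ([isc()]), ranked ([rank_alignments()]) and pruned for overlap
#' ([prune_overlaps()]).
#'
#' @param networks named list of 2 or more non-empty `tsppi_network`
#'   objects sharing a homology scheme.
#' @param homology a `homology_map`; label identity by default.
#' @param params an [alignment_parameters] object.
#' @return list of [alignment] objects, best first (possibly empty).
#' @export
align_networks <- function(networks, homology = homology_by_label(),
                           params = alignment_parameters()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- family_index(networks, homology, params)
  results <- list()
  for (a in seq_len(params$attempts)) {
    members <- run_gibbs_seed(idx, params)
    al <- alignment(matrix(members, nrow = 1,
                           dimnames = list(NULL, idx$nets)),
                    column_fold(idx, members))
    for (it in seq_len(params$refine_iterations)) {
      al <- extend_engine(idx, al, params)
      al <- remove_worst_engine(idx, al)
    }
    al <- extend_engine(idx, al, params)
    if (nrow(al$columns) < params$min_alignment_size) next
    if (al$avg_max_logfold < params$max_logfold_threshold) next
    al$isc <- isc_engine(idx$adj, al$columns)
    results[[length(results) + 1L]] <- al
  }
  prune_overlaps(rank_alignments(results), params$overlap_threshold)
}
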