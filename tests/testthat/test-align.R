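two_gene_family <- function() {
  # nets share only gene A (degree 1 in both)
  n1 <- make_net(c(A = 8, B = 4),
                 data.frame(gene_a = "A", gene_b = "B", weight = 0.5),
                 name = "n1")
  n2 <- make_net(c(A = 2, C = 4),
                 data.frame(gene_a = "A", gene_b = "C", weight = 0.5),
                 name = "n2")
  list(n1 = n1, n2 = n2)
}

test_that("bootstrap returns the only homologous column deterministically", {
  fam <- two_gene_family()
  seed <- bootstrap_seed(fam, params = alignment_parameters(seed = 1))
  expect_equal(unname(seed$columns[1, ]), c("A", "A"))
  expect_equal(seed$max_logfold, 2)  # 8 vs 2

  expect_error(
    bootstrap_seed(fam, params = alignment_parameters(sigma = 5, seed = 1)),
    "no seed candidates")

  s1 <- bootstrap_seed(fam, params = alignment_parameters(seed = 9))
  s2 <- bootstrap_seed(fam, params = alignment_parameters(seed = 9))
  expect_identical(s1$columns, s2$columns)
})

test_that("extension adds only adjacent columns meeting the divergence bar", {
  # path A-B-C in both networks; folds: A 2, B 1, C 0
  wmat <- cbind(c(8, 8, 5), c(2, 4, 5))
  rownames(wmat) <- c("A", "B", "C")
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      weight = 0.5)
  fam <- make_family(wmat, edges)
  start <- alignment(matrix(c("A", "A"), ncol = 2,
                            dimnames = list(NULL, names(fam))),
                     max_log_fold(wmat["A", ]))
  grown <- extend_alignment(start, fam,
                            params = alignment_parameters(
                              max_logfold_threshold = 0.6, seed = 3))
  # B (fold 1) is admissible, C (fold 0) is not
  expect_setequal(grown$columns[, 1], c("A", "B"))

  unchanged <- extend_alignment(start, fam,
                                params = alignment_parameters(
                                  max_logfold_threshold = 99, seed = 3))
  expect_identical(unchanged$columns, start$columns)

  # per-network induced subgraphs stay connected after extension
  for (i in seq_along(fam)) {
    sub <- igraph::induced_subgraph(fam[[i]]$graph, grown$columns[, i])
    expect_true(igraph::is_connected(sub))
  }
})

test_that("removal deletes the least divergent removable column", {
  # triangle: every column is removable
  tri <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                    weight = 0.5)
  wmat <- cbind(c(8, 8, 8), c(2, 7.5, 3))  # folds: 2.0, ~0.09, ~1.4
  rownames(wmat) <- c("A", "B", "C")
  fam <- make_family(wmat, tri)
  al <- alignment(matrix(rep(c("A", "B", "C"), 2), ncol = 2,
                         dimnames = list(NULL, names(fam))),
                  apply(wmat, 1, max_log_fold))
  out <- remove_worst(al, fam)
  expect_setequal(out$columns[, 1], c("A", "C"))

  # path A-B-C where the middle column B is the least divergent:
  # removing it would disconnect, so the weakest end column goes instead
  path <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                     weight = 0.5)
  fam2 <- make_family(wmat, path)
  al2 <- alignment(al$columns, al$max_logfold)
  out2 <- remove_worst(al2, fam2)
  expect_setequal(out2$columns[, 1], c("A", "B"))  # C removed, not B

  single <- alignment(matrix(c("A", "A"), ncol = 2,
                             dimnames = list(NULL, names(fam))), 2)
  expect_identical(remove_worst(single, fam)$columns, single$columns)
})

test_that("ranking and overlap pruning are deterministic", {
  cols <- function(g, nets = c("n1", "n2")) {
    matrix(rep(g, 2), ncol = 2, dimnames = list(NULL, nets))
  }
  a <- alignment(cols(c("A", "B", "C")), c(1, 1, 1), isc = 0.9)
  b <- alignment(cols(c("D", "E", "F")), c(2, 2, 2), isc = 0.4)
  expect_equal(rank_alignments(list(b, a))[[1]]$isc, 0.9)

  b2 <- alignment(cols(c("D", "E", "F")), c(2, 2, 2), isc = 0.9)
  ranked <- rank_alignments(list(a, b2))
  expect_equal(ranked[[1]]$avg_max_logfold, 2)

  tied <- rank_alignments(list(b2, alignment(cols(c("A", "B", "C")),
                                             c(2, 2, 2), isc = 0.9)))
  expect_equal(unname(tied[[1]]$columns[, 1]), c("A", "B", "C"))

  # disjoint alignments survive any threshold; duplicates do not
  expect_length(prune_overlaps(list(a, b), 0), 2L)
  expect_length(prune_overlaps(list(a, a), 0.5), 1L)
  expect_length(prune_overlaps(list(a, a), 1), 2L)
  # overlap 2/3 exceeds the 0.5 threshold, so the second alignment goes
  kept <- prune_overlaps(list(a, alignment(cols(c("A", "B", "Z")),
                                           c(1, 1, 1), isc = 0.5)), 0.5)
  expect_length(kept, 1L)
  expect_true(all(vapply(prune_overlaps(list(a, a, b), 0.5),
                         function(x) nrow(x$columns), numeric(1)) == 3))
})

test_that("identical equal-weight networks yield no alignment", {
  wmat <- matrix(8, nrow = 5, ncol = 3,
                 dimnames = list(paste0("G", 1:5), NULL))
  edges <- data.frame(gene_a = paste0("G", 1:4),
                      gene_b = paste0("G", 2:5), weight = 0.5)
  fam <- make_family(wmat, edges)
  out <- align_networks(fam, params = alignment_parameters(
    attempts = 10, seed = 5))
  expect_length(out, 0L)
})

test_that("alignment is reproducible and recovers a planted module", {
  inst <- generate_instance(synthetic_spec(seed = 21))
  params <- alignment_parameters(seed = 31, attempts = 20)
  out1 <- align_networks(inst$networks, params = params)
  out2 <- align_networks(inst$networks, params = params)
  expect_identical(lapply(out1, `[[`, "columns"),
                   lapply(out2, `[[`, "columns"))

  sc <- score_recovery(out1, inst$truth)
  expect_gte(sc$f1, 0.8)

  for (al in out1) {
    expect_gte(al$avg_max_logfold, 0.6)
    expect_gte(nrow(al$columns), 3)
    expect_true(al$isc >= 0 && al$isc <= 1)
    for (i in seq_along(al$networks)) {
      expect_false(anyDuplicated(al$columns[, i]) > 0)  # one-to-one
      sub <- igraph::induced_subgraph(
        inst$networks[[al$networks[i]]]$graph, al$columns[, i])
      expect_true(igraph::is_connected(sub))
    }
  }
})

test_that("raising the divergence threshold never grows the top alignment", {
  sizes <- sapply(1:6, function(s) {
    inst <- generate_instance(synthetic_spec(seed = 300 + s))
    vapply(c(0.6, 2.05, 3), function(th) {
      out <- align_networks(inst$networks, params = alignment_parameters(
        max_logfold_threshold = th, attempts = 10, seed = 400 + s))
      if (length(out) == 0) 0L else nrow(out[[1]]$columns)
    }, integer(1))
  })
  means <- rowMeans(sizes)
  expect_true(all(diff(means) <= 0))
})

test_that("file-based homology steers which nodes may align", {
  # disjoint label spaces: label identity would find nothing
  n1 <- make_net(c(X1 = 8, X2 = 8, X3 = 5),
                 data.frame(gene_a = c("X1", "X2"), gene_b = c("X2", "X3"),
                            weight = 0.5), name = "n1")
  n2 <- make_net(c(Y1 = 2, Y2 = 2, Y3 = 5),
                 data.frame(gene_a = c("Y1", "Y2"), gene_b = c("Y2", "Y3"),
                            weight = 0.5), name = "n2")
  fam <- list(n1 = n1, n2 = n2)
  h <- read_homology_file(
    write_lines_tmp(c("X1\tn1\tY1\tn2\t1.0",
                      "X2\tn1\tY2\tn2\t1.0",
                      "X3\tn1\tY3\tn2\t1.0")),
    c("n1", "n2"))
  out <- align_networks(fam, homology = h,
                        params = alignment_parameters(
                          min_alignment_size = 2, attempts = 10, seed = 2))
  expect_gte(length(out), 1L)
  top <- out[[1]]
  expect_setequal(top$columns[, "n1"], c("X1", "X2"))
  expect_setequal(top$columns[, "n2"], c("Y1", "Y2"))

  expect_error(align_networks(fam), "no seed candidates")
  expect_error(align_networks(fam["n1"]), "at least two")
})
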