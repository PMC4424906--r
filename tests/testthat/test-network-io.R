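test_that("interaction files parse, canonicalize and validate weights", {
  p <- write_lines_tmp(c("# a comment", "", "TP53\tMDM2\t0.9",
                         "brca1 \tBRCA2\t0.25"))
  recs <- read_interaction_file(p, weighted = TRUE)
  expect_equal(recs$gene_a, c("TP53", "BRCA1"))
  expect_equal(recs$gene_b, c("MDM2", "BRCA2"))
  expect_equal(recs$weight, c(0.9, 0.25))

  p2 <- write_lines_tmp("BRCA1 BRCA2")
  recs2 <- read_interaction_file(p2, weighted = FALSE)
  expect_equal(recs2$gene_a, "BRCA1")
  expect_true(is.na(recs2$weight))

  expect_error(read_interaction_file(write_lines_tmp("A\tB\t1.5"),
                                     weighted = TRUE), "outside")
  expect_error(read_interaction_file(write_lines_tmp(c("A\tB\t0.5", "C")),
                                     weighted = TRUE), "line 2")
})

test_that("expression matrices parse with duplicate-gene averaging", {
  p <- write_lines_tmp(c("liver\tkidney\tbrain",
                         "G1\t1\t2\t3",
                         "G2\t4\t5\t6"))
  m <- read_expression_matrix(p)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(colnames(m), c("liver", "kidney", "brain"))
  expect_equal(unname(m["G2", "kidney"]), 5)

  # corner cell above the gene column is ignored
  p_corner <- write_lines_tmp(c("gene\tliver\tkidney",
                                "G1\t1\t2"))
  expect_equal(colnames(read_expression_matrix(p_corner)),
               c("liver", "kidney"))

  p_dup <- write_lines_tmp(c("T1\tT2", "G\t4\t1", "G\t6\t3"))
  m_dup <- read_expression_matrix(p_dup)
  expect_equal(unname(m_dup["G", ]), c(5, 2))

  # a gene row with too few cells for the declared conditions
  expect_error(read_expression_matrix(
    write_lines_tmp(c("id\tT1\tT2\tT3", "G1\t1\t2"))), "cells")
  expect_error(read_expression_matrix(
    write_lines_tmp(c("T1\tT2", "G1\t1\t2", "G2\t1"))), "cells")
  expect_error(read_expression_matrix(
    write_lines_tmp(c("T1\tT2", "G1\t1\tabc"))), "non-numeric.*T2")
  expect_error(read_expression_matrix(
    write_lines_tmp(c("T1\tT1", "G1\t1\t2"))), "duplicate condition")
})

test_that("TS-PPI reader collapses multi-edges and builds node weights", {
  p <- write_lines_tmp(c("A\tB\tliver\t5\t6\t0.8",
                         "A\tB\tkidney\t5\t6\t0.4"))
  net <- read_tsppi_network(p, name = "toy")
  ed <- tsppi_edges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, 0.6)
  expect_equal(ed$label, "liver;kidney")
  expect_setequal(net$conditions, c("liver", "kidney"))

  p1 <- write_lines_tmp("A\tB\tliver\t5\t6\t0.8")
  net1 <- read_tsppi_network(p1)
  expect_equal(sort(tsppi_nodes(net1)$gene), c("A", "B"))
  expect_equal(unname(node_weights(net1)[c("A", "B")]), c(5, 6))
  expect_equal(nrow(tsppi_edges(net1)), 1L)

  # a file containing only a self-loop leaves an empty graph -> error
  expect_error(
    suppressWarnings(read_tsppi_network(
      write_lines_tmp("A\tA\tliver\t5\t5\t1.0"))),
    "self-loop")
  expect_warning(
    read_tsppi_network(write_lines_tmp(c("A\tA\tliver\t5\t5\t1.0",
                                         "A\tB\tliver\t5\t6\t0.8"))),
    "self-loop")
  expect_error(read_tsppi_network(
    write_lines_tmp("A\tB\tliver\t0\t6\t0.8")), "non-positive")
  expect_error(read_tsppi_network(write_lines_tmp("# only comments")),
               "empty")
})

test_that("TS-PPI files round-trip to an identical network", {
  inst <- generate_instance(synthetic_spec(n_networks = 2, n_genes = 40,
                                           seed = 7))
  net <- inst$networks[[1]]
  path <- tempfile(fileext = ".tsv")
  write_tsppi_network(net, path)
  back <- read_tsppi_network(path, name = net$name)

  expect_setequal(tsppi_nodes(back)$gene, tsppi_nodes(net)$gene)
  w0 <- node_weights(net)
  w1 <- node_weights(back)[names(w0)]
  expect_equal(unname(w1), unname(w0), tolerance = 1e-9)

  e0 <- tsppi_edges(net)
  e1 <- tsppi_edges(back)
  k0 <- paste(pmin(e0$gene_a, e0$gene_b), pmax(e0$gene_a, e0$gene_b))
  k1 <- paste(pmin(e1$gene_a, e1$gene_b), pmax(e1$gene_a, e1$gene_b))
  expect_setequal(k1, k0)
  expect_equal(e1$weight[match(k0, k1)], e0$weight, tolerance = 1e-9)

  # reading always yields a simple graph
  expect_true(igraph::is_simple(back$graph))
})

test_that("homology files build a symmetric score map", {
  p <- write_lines_tmp(c("TP53\tnet1\tTP53\tnet2\t1.0",
                         "MDM2\tnet1\tMDM4\tnet2\t0.7"))
  h <- read_homology_file(p, c("net1", "net2"))
  expect_equal(homology_pair_score(h, "net1", "TP53", "net2", "TP53"), 1.0)
  expect_equal(homology_pair_score(h, "net2", "TP53", "net1", "TP53"), 1.0)
  expect_equal(homology_pair_score(h, "net2", "MDM4", "net1", "MDM2"), 0.7)
  expect_equal(homology_pair_score(h, "net1", "TP53", "net2", "MDM4"), 0)

  expect_error(read_homology_file(
    write_lines_tmp("A\tnet1\tB\tnet2\t0"), c("net1", "net2")),
    "positive")
  expect_error(read_homology_file(
    write_lines_tmp("A\tnet9\tB\tnet2\t1"), c("net1", "net2")),
    "unknown network")
  expect_error(read_homology_file(
    write_lines_tmp("A\tnet1\tB\tnet1\t1"), c("net1", "net2")),
    "single network")

  # 3-column dialect with unambiguous node sets
  h3 <- read_homology_file(
    write_lines_tmp("X1\tY1\t0.9"), c("n1", "n2"),
    node_sets = list(n1 = c("X1", "X2"), n2 = c("Y1", "Y2")))
  expect_equal(homology_pair_score(h3, "n1", "X1", "n2", "Y1"), 0.9)
  expect_error(read_homology_file(
    write_lines_tmp("X1\tY1\t0.9"), c("n1", "n2"),
    node_sets = list(n1 = c("X1", "Y1"), n2 = c("Y1"))), "ambiguous")
})

test_that("alignment reports contain the mapping matrix and an index", {
  wmat <- matrix(c(8, 4, 2, 8, 4, 2), ncol = 2,
                 dimnames = list(c("A", "B", "C"), NULL))
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      weight = 0.5)
  fam <- make_family(wmat, edges)
  al <- alignment(matrix(c("A", "B", "C", "A", "B", "C"), ncol = 2,
                         dimnames = list(NULL, names(fam))),
                  c(1, 2, 3), isc = 1)
  out <- tempfile()
  write_alignment_report(list(al), fam, out)
  map <- read.delim(file.path(out, "alignment_001_mapping.tsv"),
                    check.names = FALSE)
  expect_equal(dim(map), c(3L, 3L))  # 3 aligned rows, 2 networks + fold
  expect_equal(names(map)[1:2], c("net1", "net2"))
  index <- read.delim(file.path(out, "index.tsv"))
  expect_equal(index$size, 3L)

  report <- readLines(file.path(out, "alignment_001.txt"))
  expect_true(any(grepl("^size\t3$", report)))
  expect_true(any(grepl("^## mapping$", report)))

  expect_error(write_alignment_report(list(), fam, tempfile()),
               "no alignments")
  out2 <- tempfile()
  write_alignment_report(list(al, al), fam, out2)
  expect_true(file.exists(file.path(out2, "alignment_002.txt")))
})
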