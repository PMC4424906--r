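# Readers and writers for the tool's tab-delimited formats.  All readers
# skip blank lines and lines starting with '#', report errors with the
# 1-based line number of the offending line, and canonicalize gene symbols
# to upper case.  Parsing uses the decimal point only (locale-independent).

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_number <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !(trimws(x) %in% "NA")
  if (any(bad))
    stop(sprintf("line %d: %s '%s' is not a number",
                 lineno[bad][1L], what, x[bad][1L]))
  v
}

#' Read an interaction dataset file
#'
#' Interaction datasets are tab- or whitespace-delimited files with two
#' columns (gene pair) for unweighted datasets, or three columns (gene
#' pair, weight in \[0, 1\]) for weighted ones.  Self-loops may appear in
#' source files; they are kept here and dropped when datasets are merged.
#'
#' @param path file path.
#' @param weighted logical; does the file carry a weight column?
#' @return data frame with columns `gene_a`, `gene_b`, `weight` (`NA` for
#'   unweighted datasets).
#' @export
read_interaction_file <- function(path, weighted = FALSE) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0) stop("no interaction records in ", path)
  fields <- strsplit(trimws(d$lines), "[ \t]+")
  want <- if (weighted) 3L else 2L
  nf <- lengths(fields)
  if (any(nf != want))
    stop(sprintf("line %d: expected %d fields, found %d",
                 d$lineno[nf != want][1L], want, nf[nf != want][1L]))
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  weight <- if (weighted) {
    w <- parse_number(m[, 3L], "weight", d$lineno)
    out_of_range <- !is.na(w) & (w < 0 | w > 1)
    if (any(out_of_range))
      stop(sprintf("line %d: weight %s outside [0, 1]",
                   d$lineno[out_of_range][1L], m[out_of_range, 3L][1L]))
    w
  } else rep(NA_real_, nrow(m))
  data.frame(gene_a = canonical_gene(m[, 1L]),
             gene_b = canonical_gene(m[, 2L]),
             weight = weight, stringsAsFactors = FALSE)
}

#' Read an expression matrix file
#'
#' Expression data come as a tab-delimited matrix: the first row lists the
#' tissue/tumor names (an optional corner cell above the gene column is
#' ignored), the first column lists gene symbols, and cells hold
#' non-negative expression values.  Duplicate gene rows are merged by
#' arithmetic mean on load.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), conditions in columns
#'   (colnames).
#' @export
read_expression_matrix <- function(path) {
  d <- read_data_lines(path)
  if (length(d$lines) < 2)
    stop("expression matrix needs a header row and at least one gene row")
  rows <- strsplit(d$lines, "\t", fixed = TRUE)
  header <- trimws(rows[[1L]])
  body <- rows[-1L]
  lns <- d$lineno[-1L]
  width <- length(body[[1L]])
  if (width < 2) stop("expression matrix needs at least one value column")
  if (length(header) == width) {
    conditions <- header[-1L]          # corner cell present, ignored
  } else if (length(header) == width - 1L) {
    conditions <- header
  } else {
    stop(sprintf(
      "header has %d fields but data rows have %d cells (line %d)",
      length(header), width, lns[1L]))
  }
  if (anyDuplicated(conditions))
    stop("duplicate condition name: ",
         conditions[duplicated(conditions)][1L])
  nf <- lengths(body)
  if (any(nf != width))
    stop(sprintf("line %d: row has %d cells, expected %d",
                 lns[nf != width][1L], nf[nf != width][1L], width))
  genes <- canonical_gene(vapply(body, `[`, character(1), 1L))
  vals <- matrix(NA_real_, nrow = length(body), ncol = width - 1L)
  for (i in seq_along(body)) {
    row <- body[[i]][-1L]
    v <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(v) & !(trimws(row) %in% "NA"))
    if (length(bad) > 0)
      stop(sprintf(
        "line %d: non-numeric value '%s' in column '%s'",
        lns[i], row[bad[1L]], conditions[bad[1L]]))
    vals[i, ] <- v
  }
  if (any(vals < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  colnames(vals) <- conditions
  if (anyDuplicated(genes)) {
    n <- rowsum(1 - is.na(vals) + 0, genes)
    s <- rowsum(ifelse(is.na(vals), 0, vals), genes)
    vals <- s / ifelse(n == 0, NA_real_, n)
  } else {
    rownames(vals) <- genes
  }
  vals
}

#' Read a TS-PPI network file
#'
#' Network files carry one tab-separated record per (interaction, tissue):
#' `gene_a  gene_b  tissue  expr_a  expr_b  weight`.  Multi-edges between
#' the same gene pair (for example from different tissues) are collapsed
#' into a single edge whose weight is the mean of the record weights and
#' whose label is the concatenation of the record tissues (separator
#' `";"`).  The node weight of a gene is the mean of the expression values
#' in the records mentioning it, with a warning if those values disagree.
#' Self-loop records are dropped with a warning.
#'
#' @param path file path.
#' @param name network label; defaults to the file name without extension.
#' @return a [tsppi_network].
#' @export
read_tsppi_network <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  d <- read_data_lines(path)
  if (length(d$lines) == 0) stop("empty TS-PPI network file: ", path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop(sprintf("line %d: expected 6 tab-separated fields, found %d",
                 d$lineno[nf != 6L][1L], nf[nf != 6L][1L]))
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  rec <- data.frame(
    gene_a = canonical_gene(m[, 1L]),
    gene_b = canonical_gene(m[, 2L]),
    tissue = trimws(m[, 3L]),
    expr_a = parse_number(m[, 4L], "expression value", d$lineno),
    expr_b = parse_number(m[, 5L], "expression value", d$lineno),
    weight = parse_number(m[, 6L], "weight", d$lineno),
    stringsAsFactors = FALSE)
  bad_expr <- is.na(rec$expr_a) | is.na(rec$expr_b) |
    rec$expr_a <= 0 | rec$expr_b <= 0
  if (any(bad_expr))
    stop(sprintf("line %d: non-positive expression score",
                 d$lineno[bad_expr][1L]))
  if (any(is.na(rec$weight) | rec$weight < 0 | rec$weight > 1))
    stop(sprintf("line %d: interaction weight outside [0, 1]",
                 d$lineno[is.na(rec$weight) | rec$weight < 0 |
                            rec$weight > 1][1L]))
  loops <- rec$gene_a == rec$gene_b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop record(s) in %s",
                    sum(loops), path))
    rec <- rec[!loops, , drop = FALSE]
  }
  if (nrow(rec) == 0)
    stop("no interactions left after self-loop removal in ", path)

  key <- pair_key(rec$gene_a, rec$gene_b)
  groups <- split(seq_len(nrow(rec)), key)
  edges <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(gene_a = min(rec$gene_a[ix[1L]], rec$gene_b[ix[1L]]),
               gene_b = max(rec$gene_a[ix[1L]], rec$gene_b[ix[1L]]),
               weight = mean(rec$weight[ix]),
               label = paste(rec$tissue[ix], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL

  expr_obs <- data.frame(
    gene = c(rec$gene_a, rec$gene_b),
    expr = c(rec$expr_a, rec$expr_b), stringsAsFactors = FALSE)
  by_gene <- split(expr_obs$expr, expr_obs$gene)
  spread <- vapply(by_gene, function(v) max(v) - min(v), numeric(1))
  if (any(spread > 1e-6))
    warning("inconsistent expression values for gene(s) ",
            paste(head(names(by_gene)[spread > 1e-6], 3), collapse = ", "),
            "; using the mean")
  nodes <- data.frame(gene = names(by_gene),
                      weight = vapply(by_gene, mean, numeric(1)),
                      stringsAsFactors = FALSE)
  tsppi_network(nodes, edges, name = name,
                conditions = unique(rec$tissue))
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write a TS-PPI network file
#'
#' Inverse of [read_tsppi_network()]: one tab-separated record per edge with
#' fields `gene_a  gene_b  tissue  expr_a  expr_b  weight`, where the
#' expression fields are the endpoint node weights.
#'
#' @param net a [tsppi_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsppi_network <- function(net, path) {
  ed <- tsppi_edges(net)
  wts <- node_weights(net)
  tissue <- ifelse(is.na(ed$label) | ed$label == "",
                   if (length(net$conditions) > 0) net$conditions[1L]
                   else "unspecified",
                   ed$label)
  lines <- c("# gene_a\tgene_b\ttissue\texpr_a\texpr_b\tweight",
             sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                     ed$gene_a, ed$gene_b, tissue,
                     format_num(unname(wts[ed$gene_a])),
                     format_num(unname(wts[ed$gene_b])),
                     format_num(ed$weight)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a homology score file
#'
#' Each row declares a pair of nodes of *different* networks that may be
#' aligned, with a positive score.  The native dialect has five
#' tab-separated columns: `node_a  network_a  node_b  network_b  score`.  A
#' three-column fallback (`node_a  node_b  score`) is accepted when
#' `node_sets` is supplied and every node label occurs in exactly one
#' network, so membership can be inferred unambiguously.
#'
#' @param path file path.
#' @param network_names declared network names; rows naming any other
#'   network are an error.
#' @param node_sets optional named list (by network) of node label vectors,
#'   required for the three-column dialect.
#' @return a `homology_map` with symmetric lookup
#'   (see [homology_pair_score()]).
#' @export
read_homology_file <- function(path, network_names, node_sets = NULL) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0) stop("empty homology file: ", path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 5L)) {
    m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
    node_a <- canonical_gene(m[, 1L]); net_a <- trimws(m[, 2L])
    node_b <- canonical_gene(m[, 3L]); net_b <- trimws(m[, 4L])
    score <- parse_number(m[, 5L], "homology score", d$lineno)
  } else if (all(nf == 3L)) {
    if (is.null(node_sets))
      stop("three-column homology file needs 'node_sets' to infer ",
           "which network each node belongs to")
    m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
    node_a <- canonical_gene(m[, 1L])
    node_b <- canonical_gene(m[, 2L])
    score <- parse_number(m[, 3L], "homology score", d$lineno)
    find_net <- function(node, lineno) {
      hit <- names(node_sets)[vapply(node_sets, function(s) node %in% s,
                                     logical(1))]
      if (length(hit) != 1L)
        stop(sprintf(
          "line %d: node '%s' is %s across networks; use the 5-column format",
          lineno, node,
          if (length(hit) == 0L) "unknown" else "ambiguous"))
      hit
    }
    net_a <- mapply(find_net, node_a, d$lineno)
    net_b <- mapply(find_net, node_b, d$lineno)
  } else {
    stop(sprintf("line %d: expected 3 or 5 tab-separated fields, found %d",
                 d$lineno[!(nf %in% c(3L, 5L))][1L],
                 nf[!(nf %in% c(3L, 5L))][1L]))
  }
  unknown <- !(net_a %in% network_names) | !(net_b %in% network_names)
  if (any(unknown))
    stop(sprintf("line %d: unknown network name '%s'",
                 d$lineno[unknown][1L],
                 setdiff(c(net_a[unknown], net_b[unknown]),
                         network_names)[1L]))
  same <- net_a == net_b
  if (any(same))
    stop(sprintf("line %d: homology pair within a single network",
                 d$lineno[same][1L]))
  bad <- is.na(score) | score <= 0
  if (any(bad))
    stop(sprintf("line %d: homology score must be positive",
                 d$lineno[bad][1L]))
  keys <- homology_key(net_a, node_a, net_b, node_b)
  scores <- tapply(score, keys, mean)
  structure(list(type = "file",
                 scores = setNames(as.numeric(scores), names(scores)),
                 networks = network_names),
            class = "homology_map")
}

#' Write an alignment report archive
#'
#' Writes one plain-text file per alignment (node lists with weights and
#' edge lists with weights and labels for each aligned subnetwork, the
#' mapping matrix with one row per aligned column and one column per
#' network, the size, the average MaxLogFold and the ISC score), a
#' machine-readable mapping TSV per alignment, and an `index.tsv` with one
#' row per alignment (`rank  size  avg_max_logfold  isc  file`).
#'
#' @param alignments non-empty list of [alignment] objects, already ranked.
#' @param networks named list of `tsppi_network` objects the alignments
#'   refer to.
#' @param path output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_alignment_report <- function(alignments, networks, path) {
  if (length(alignments) == 0) stop("no alignments to write")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  files <- character(0)
  index <- data.frame(rank = integer(), size = integer(),
                      avg_max_logfold = character(), isc = character(),
                      file = character())
  for (k in seq_along(alignments)) {
    al <- alignments[[k]]
    fname <- sprintf("alignment_%03d.txt", k)
    lines <- c(
      sprintf("# local alignment %d", k),
      sprintf("size\t%d", nrow(al$columns)),
      sprintf("avg_max_logfold\t%s", format_num(al$avg_max_logfold)),
      sprintf("isc\t%s", format_num(al$isc)),
      "")
    for (i in seq_along(al$networks)) {
      nm <- al$networks[i]
      net <- networks[[nm]]
      members <- al$columns[, i]
      sub <- igraph::induced_subgraph(net$graph, members)
      lines <- c(lines, sprintf("## network %s: nodes", nm),
                 sprintf("%s\t%s", igraph::V(sub)$name,
                         format_num(igraph::V(sub)$weight)))
      el <- igraph::as_edgelist(sub)
      lines <- c(lines, sprintf("## network %s: edges", nm))
      if (nrow(el) > 0) {
        lab <- igraph::E(sub)$label
        if (is.null(lab)) lab <- rep(NA_character_, nrow(el))
        lines <- c(lines, sprintf("%s\t%s\t%s\t%s", el[, 1L], el[, 2L],
                                  format_num(igraph::E(sub)$weight),
                                  ifelse(is.na(lab), "NA", lab)))
      }
      lines <- c(lines, "")
    }
    lines <- c(lines, "## mapping",
               paste(c(al$networks, "max_logfold"), collapse = "\t"),
               vapply(seq_len(nrow(al$columns)), function(r) {
                 paste(c(al$columns[r, ], format_num(al$max_logfold[r])),
                       collapse = "\t")
               }, character(1)))
    writeLines(lines, file.path(path, fname))
    map_name <- sprintf("alignment_%03d_mapping.tsv", k)
    map <- data.frame(al$columns, max_logfold = al$max_logfold,
                      check.names = FALSE)
    write.table(map, file.path(path, map_name), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, fname, map_name)
    index <- rbind(index, data.frame(
      rank = k, size = nrow(al$columns),
      avg_max_logfold = format_num(al$avg_max_logfold),
      isc = format_num(al$isc), file = fname))
  }
  write.table(index, file.path(path, "index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(path, c(files, "index.tsv")))
}
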