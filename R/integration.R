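# Integration of heterogeneous interaction datasets into one global
# gene-interaction network, and of expression datasets into unified
# per-(gene, condition) expression scores.

#' Merge interaction datasets into a global gene-interaction network
#'
#' The global network is the union of all interactions reported in at least
#' one dataset.  Every edge carries the average weight across the datasets
#' that report it and the dataset coverage (fraction of integrated datasets
#' reporting it).  A dataset that reports an edge without a weight
#' (unweighted dataset, `NA` weight) contributes weight 1.0 to the average:
#' an unqualified report is read as a certain interaction, which is also
#' what makes the upper end of the global weight range reachable.
#' Self-loops are dropped; duplicate records within one dataset count once
#' (their weights are averaged).
#'
#' @param datasets named list of interaction record data frames as returned
#'   by [read_interaction_file()] (columns `gene_a`, `gene_b`, `weight`).
#' @return an object of class `global_network` with an `edges` data frame
#'   (`gene_a`, `gene_b`, `avg_weight`, `coverage`, `n_reporting`), a
#'   parallel `weights` list of per-dataset weights, `dataset_names` and
#'   `n_datasets`.
#' @export
merge_interaction_datasets <- function(datasets) {
  if (length(datasets) == 0)
    stop("at least one interaction dataset is required")
  if (is.null(names(datasets)) || any(names(datasets) == "") ||
      anyDuplicated(names(datasets)))
    stop("datasets must have unique non-empty names")
  nd <- length(datasets)

  per_ds <- lapply(datasets, function(d) {
    a <- canonical_gene(as.character(d$gene_a))
    b <- canonical_gene(as.character(d$gene_b))
    w <- if ("weight" %in% names(d)) as.numeric(d$weight)
         else rep(NA_real_, length(a))
    keep <- a != b
    a <- a[keep]; b <- b[keep]; w <- w[keep]
    key <- pair_key(a, b)
    # duplicate records within one dataset: single report, averaged weight
    agg <- tapply(w, key, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    setNames(as.numeric(agg), names(agg))
  })

  all_keys <- sort(unique(unlist(lapply(per_ds, names), use.names = FALSE)))
  if (length(all_keys) == 0)
    stop("no interactions left after self-loop removal")
  report <- vapply(per_ds, function(v) all_keys %in% names(v), logical(length(all_keys)))
  report <- matrix(report, nrow = length(all_keys),
                   dimnames = list(all_keys, names(datasets)))
  wmat <- vapply(per_ds, function(v) unname(v[all_keys]),
                 numeric(length(all_keys)))
  wmat <- matrix(wmat, nrow = length(all_keys),
                 dimnames = list(all_keys, names(datasets)))
  contrib <- ifelse(report, ifelse(is.na(wmat), 1, wmat), NA_real_)
  n_rep <- rowSums(report)
  avg_w <- rowSums(contrib, na.rm = TRUE) / n_rep

  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    avg_weight = unname(avg_w),
    coverage = unname(n_rep / nd),
    n_reporting = unname(as.integer(n_rep)),
    stringsAsFactors = FALSE)
  weights <- lapply(seq_along(all_keys), function(i) {
    w <- wmat[i, report[i, ], drop = TRUE]
    setNames(as.numeric(w), colnames(report)[report[i, ]])
  })
  structure(list(edges = edges, weights = weights,
                 dataset_names = names(datasets), n_datasets = nd),
            class = "global_network")
}

#' @export
print.global_network <- function(x, ...) {
  cat(sprintf(
    "Global gene-interaction network: %d genes, %d edges, %d dataset(s)\n",
    length(unique(c(x$edges$gene_a, x$edges$gene_b))),
    nrow(x$edges), x$n_datasets))
  invisible(x)
}

#' Log2-transform an expression matrix
#'
#' Replaces every cell `v` by `log2(v + offset)`.  The default offset of 1
#' is a pseudo-count guarding zero counts; with `offset = 0` any zero cell
#' is an error instead of silently becoming `-Inf`.
#'
#' @param matrix numeric expression matrix (genes x conditions), values
#'   >= 0.
#' @param offset small non-negative pseudo-count (default 1).
#' @return transformed matrix with the same dimnames.
#' @export
log2_transform <- function(matrix, offset = 1) {
  if (!is.numeric(matrix)) stop("expression matrix must be numeric")
  if (any(matrix < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  if (any(matrix + offset <= 0, na.rm = TRUE))
    stop("cell with value ", min(matrix, na.rm = TRUE),
         " and offset ", offset, " would produce log2 of a non-positive ",
         "number; use a positive offset")
  out <- log2(matrix + offset)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (condition) to share the same distribution of
#' values: each value is replaced by the mean, across columns, of the
#' values at its rank (the Bolstad procedure; ties receive the mean of the
#' rank means they span).  Backed by `limma::normalizeQuantiles`.
#'
#' @param matrix numeric matrix with at least 2 columns and no missing
#'   cells.  A single-column matrix is returned unchanged with a warning.
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.numeric(matrix) || !is.matrix(matrix))
    stop("expression matrix must be a numeric matrix")
  if (ncol(matrix) < 2) {
    warning("quantile normalization needs at least 2 columns; ",
            "matrix returned unchanged")
    return(matrix)
  }
  if (anyNA(matrix))
    stop("quantile normalization requires a complete matrix (no NA cells)")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Collapse probe-level rows to gene-level rows
#'
#' The expression of a gene in a tissue is the mean expression of the
#' probes mapping to that gene.  Probes without a mapping are dropped.
#'
#' @param matrix numeric matrix with probe identifiers as rownames.
#' @param probe_to_gene named character vector, probe -> gene symbol (each
#'   probe maps to at most one gene).
#' @return matrix with one row per gene.
#' @export
average_duplicate_probes <- function(matrix, probe_to_gene) {
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene)))
    stop("probe_to_gene must be a named vector (probe -> gene)")
  keep <- rownames(matrix) %in% names(probe_to_gene)
  m <- matrix[keep, , drop = FALSE]
  genes <- canonical_gene(unname(probe_to_gene[rownames(m)]))
  if (nrow(m) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = ncol(matrix),
                  dimnames = list(character(0), colnames(matrix))))
  n <- rowsum((!is.na(m)) + 0, genes)
  s <- rowsum(ifelse(is.na(m), 0, m), genes)
  s / ifelse(n == 0, NA_real_, n)
}

#' Build a unified expression table from normalized datasets
#'
#' Each (gene, condition) pair gets one positive expression score: the
#' arithmetic mean of the normalized values across the datasets that report
#' the pair.  A dataset that does not report a pair simply does not vote;
#' pairs reported nowhere are absent from the table.
#'
#' @param datasets named list of normalized expression matrices (genes x
#'   conditions; `NA` cells mean "not reported").
#' @return an object of class `expression_table`.
#' @export
build_expression_table <- function(datasets) {
  if (length(datasets) == 0)
    stop("at least one expression dataset is required")
  if (is.null(names(datasets)) || any(names(datasets) == "") ||
      anyDuplicated(names(datasets)))
    stop("expression datasets must have unique non-empty names")
  long <- do.call(rbind, lapply(names(datasets), function(nm) {
    m <- datasets[[nm]]
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("expression matrix '", nm, "' needs gene rownames and ",
           "condition colnames")
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(gene = canonical_gene(rownames(m)[idx[, 1L]]),
               condition = colnames(m)[idx[, 2L]],
               dataset = nm, value = m[idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0)
    stop("expression datasets contain no reported values")
  structure(list(values = long, datasets = names(datasets)),
            class = "expression_table")
}

#' Expression scores of an expression table
#'
#' @param expr an `expression_table`.
#' @return data frame (`gene`, `condition`, `score`) with one row per
#'   reported pair; the score is the mean over reporting datasets.
#' @export
expr_scores <- function(expr) {
  v <- expr$values
  agg <- tapply(v$value, paste(v$gene, v$condition, sep = "\r"), mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, character(1), 1L),
             condition = vapply(parts, `[`, character(1), 2L),
             score = as.numeric(agg), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Look up one expression score
#'
#' @param expr an `expression_table`.
#' @param gene gene symbol.
#' @param condition tissue/tumor name.
#' @return the score, or `NA` when the pair is reported by no dataset.
#' @export
expr_score <- function(expr, gene, condition) {
  v <- expr$values
  hit <- v$gene == canonical_gene(gene) & v$condition == condition
  if (!any(hit)) return(NA_real_)
  mean(v$value[hit])
}

#' Restrict an expression table to a subset of datasets
#'
#' Scores are recomputed as means over the selected datasets only; pairs
#' unreported in the subset disappear from the table.
#'
#' @param expr an `expression_table`.
#' @param subset non-empty character vector of dataset names.
#' @return a new `expression_table`.
#' @export
restrict_to_datasets <- function(expr, subset) {
  if (length(subset) == 0) stop("dataset subset must be non-empty")
  unknown <- setdiff(subset, expr$datasets)
  if (length(unknown) > 0)
    stop("unknown expression dataset: ", unknown[1L])
  structure(list(values = expr$values[expr$values$dataset %in% subset, ,
                                      drop = FALSE],
                 datasets = subset),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "Expression table: %d genes, %d conditions, %d dataset(s), %d values\n",
    length(unique(x$values$gene)), length(unique(x$values$condition)),
    length(x$datasets), nrow(x$values)))
  invisible(x)
}
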