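# Construction of TS-PPI networks from the global gene-interaction network
# and the unified expression table, under user-supplied search filters.

#' Search filter for TS-PPI construction
#'
#' All thresholds are inclusive (a value equal to the threshold passes).
#'
#' @param conditions non-empty character vector of tissue/tumor names; one
#'   network is built per condition.  Tissues and tumors are mutually
#'   exclusive in a single build: networks over normal and pathological
#'   states are built separately and then compared.
#' @param gene_list optional set of gene symbols the search is restricted
#'   to.
#' @param expression_datasets optional subset of expression dataset names
#'   over which scores are recomputed.
#' @param interaction_datasets optional subset of interaction dataset
#'   names; an edge must be reported by at least one of them.
#' @param min_expression optional minimum expression score for a gene to
#'   count as expressed.
#' @param min_edge_weight optional minimum average interaction weight in
#'   \[0, 1\].
#' @param min_coverage optional minimum dataset coverage in \[0, 1\].
#' @return an object of class `build_filter`.
#' @export
build_filter <- function(conditions, gene_list = NULL,
                         expression_datasets = NULL,
                         interaction_datasets = NULL,
                         min_expression = NULL,
                         min_edge_weight = NULL,
                         min_coverage = NULL) {
  if (length(conditions) == 0)
    stop("at least one condition (tissue/tumor) is required")
  chk01 <- function(x, what) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 ||
                        x < 0 || x > 1))
      stop(what, " must be a single value in [0, 1]")
  }
  chk01(min_edge_weight, "min_edge_weight")
  chk01(min_coverage, "min_coverage")
  if (!is.null(min_expression) &&
      (!is.numeric(min_expression) || length(min_expression) != 1))
    stop("min_expression must be a single number")
  structure(list(conditions = as.character(conditions),
                 gene_list = if (is.null(gene_list)) NULL
                             else canonical_gene(gene_list),
                 expression_datasets = expression_datasets,
                 interaction_datasets = interaction_datasets,
                 min_expression = min_expression,
                 min_edge_weight = min_edge_weight,
                 min_coverage = min_coverage),
            class = "build_filter")
}

#' Build TS-PPI networks
#'
#' For each requested condition, the TS-PPI network is the subgraph of the
#' global network induced by the genes expressed in that condition
#' (optionally above `min_expression`, within `gene_list`, with scores
#' recomputed over the selected expression datasets), keeping only edges
#' whose average weight and coverage meet their thresholds and that are
#' reported by at least one selected interaction dataset.  Both endpoints
#' of every surviving edge are expressed in the condition; expressed genes
#' with no surviving interaction (isolated nodes) are excluded.
#'
#' @param global_net a `global_network` from
#'   [merge_interaction_datasets()].
#' @param expr an `expression_table` from [build_expression_table()].
#' @param filter a [build_filter].
#' @return named list of [tsppi_network] objects, one per condition.  An
#'   empty network (with a warning) is returned for conditions where no
#'   interaction survives.
#' @export
build_tsppi <- function(global_net, expr, filter) {
  stopifnot(inherits(global_net, "global_network"),
            inherits(expr, "expression_table"),
            inherits(filter, "build_filter"))
  if (!is.null(filter$expression_datasets))
    expr <- restrict_to_datasets(expr, filter$expression_datasets)
  known_conditions <- unique(expr$values$condition)
  unknown <- setdiff(filter$conditions, known_conditions)
  if (length(unknown) > 0)
    stop("unknown condition: ", unknown[1L])
  if (!is.null(filter$interaction_datasets)) {
    bad <- setdiff(filter$interaction_datasets, global_net$dataset_names)
    if (length(bad) > 0) stop("unknown interaction dataset: ", bad[1L])
  }

  ed <- global_net$edges
  keep <- rep(TRUE, nrow(ed))
  if (!is.null(filter$min_edge_weight))
    keep <- keep & ed$avg_weight >= filter$min_edge_weight
  if (!is.null(filter$min_coverage))
    keep <- keep & ed$coverage >= filter$min_coverage
  if (!is.null(filter$interaction_datasets)) {
    keep <- keep & vapply(global_net$weights, function(w) {
      any(names(w) %in% filter$interaction_datasets)
    }, logical(1))
  }
  ed <- ed[keep, , drop = FALSE]

  scores <- expr_scores(expr)
  out <- list()
  for (cond in filter$conditions) {
    sc <- scores[scores$condition == cond, , drop = FALSE]
    if (!is.null(filter$min_expression))
      sc <- sc[sc$score >= filter$min_expression, , drop = FALSE]
    if (!is.null(filter$gene_list))
      sc <- sc[sc$gene %in% filter$gene_list, , drop = FALSE]
    expressed <- setNames(sc$score, sc$gene)
    ec <- ed[ed$gene_a %in% names(expressed) &
               ed$gene_b %in% names(expressed), , drop = FALSE]
    if (nrow(ec) == 0) {
      warning("no interaction survives the filters for condition '",
              cond, "'; returning an empty network")
      out[[cond]] <- tsppi_network(
        data.frame(gene = character(), weight = numeric()),
        data.frame(gene_a = character(), gene_b = character(),
                   weight = numeric()),
        name = cond, conditions = cond)
      next
    }
    genes <- sort(unique(c(ec$gene_a, ec$gene_b)))
    out[[cond]] <- tsppi_network(
      nodes = data.frame(gene = genes, weight = unname(expressed[genes])),
      edges = data.frame(gene_a = ec$gene_a, gene_b = ec$gene_b,
                         weight = ec$avg_weight, label = cond,
                         coverage = ec$coverage),
      name = cond, conditions = cond)
  }
  out
}
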