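#' Absolute log2 fold change between two expression values
#'
#' The expression divergence of two genes is `log2(max(a, b) / min(a, b))`:
#' symmetric in its arguments, zero iff they are equal, and non-negative.
#' Values at or below `epsilon` are clamped to `epsilon` so that degenerate
#' (near-zero) expression scores cannot produce infinities.
#'
#' @param expr_a,expr_b positive expression values (vectorized).
#' @param epsilon clamping guard for near-zero values (default `1e-6`).
#' @return non-negative numeric vector.
#' @export
log_fold <- function(expr_a, expr_b, epsilon = 1e-6) {
  if (any(is.na(expr_a)) || any(is.na(expr_b)))
    stop("log_fold: expression values must not be NA/NaN")
  if (!is.numeric(expr_a) || !is.numeric(expr_b))
    stop("log_fold: expression values must be numeric")
  a <- pmax(expr_a, epsilon)
  b <- pmax(expr_b, epsilon)
  abs(log2(a / b))
}

#' Maximum pairwise log fold change of an alignment column
#'
#' For a set of aligned genes, one per network, the column divergence is the
#' maximum of [log_fold()] over all unordered pairs, which equals the log
#' fold between the largest and smallest value.
#'
#' @param column_weights numeric vector (length >= 2) of positive expression
#'   values.
#' @param epsilon clamping guard passed to the fold computation.
#' @return non-negative scalar.
#' @export
max_log_fold <- function(column_weights, epsilon = 1e-6) {
  if (length(column_weights) < 2)
    stop("max_log_fold needs at least two expression values")
  if (any(is.na(column_weights)))
    stop("max_log_fold: expression values must not be NA/NaN")
  w <- pmax(column_weights, epsilon)
  log2(max(w) / min(w))
}

#' Gibbs sampling iteration budget
#'
#' The sampler stops once an alignment column is unchanged for `k`
#' consecutive iterations, where `k` is the largest number of iterations for
#' which the probability `((N - 1) / N)^k` that a given network is never
#' re-drawn still exceeds `alpha`.  Smaller `alpha` yields a larger budget
#' and a more thorough (slower) sampling.
#'
#' @param n_networks number of networks being aligned (integer >= 2).
#' @param alpha probability threshold in (0, 1).
#' @return integer budget `k` (0 when even a single iteration fails the
#'   probability bound).
#' @export
gibbs_iteration_budget <- function(n_networks, alpha) {
  if (!is.numeric(n_networks) || length(n_networks) != 1 ||
      n_networks < 2 || n_networks != round(n_networks))
    stop("n_networks must be a single integer >= 2")
  if (!is.numeric(alpha) || length(alpha) != 1 ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  r <- (n_networks - 1) / n_networks
  # closed form with local correction against floating-point rounding;
  # the comparison is strict: r^k must exceed alpha, equality does not count
  k <- floor(log(alpha) / log(r))
  while (k > 0 && r^k <= alpha) k <- k - 1
  while (r^(k + 1) > alpha) k <- k + 1
  as.integer(k)
}

#' Index of structural conservation of an alignment
#'
#' The fraction of aligned node pairs whose interaction is conserved in all
#' networks, among the pairs whose interaction is present in at least one
#' network.  An alignment with no interacting pair in any network scores 0.
#'
#' @param alignment an [alignment] object.
#' @param networks named list of `tsppi_network` objects, in the column
#'   order of the alignment.
#' @return scalar in \[0, 1\].
#' @export
isc <- function(alignment, networks) {
  isc_engine(lapply(networks, tsppi_adjacency), alignment$columns)
}

isc_engine <- function(adj, cols) {
  w <- nrow(cols)
  if (w < 2) return(0)
  conserved <- 0L
  present <- 0L
  for (r in seq_len(w - 1)) {
    for (s in seq(r + 1, w)) {
      hits <- vapply(seq_along(adj), function(i) {
        cols[s, i] %in% adj[[i]][[cols[r, i]]]
      }, logical(1))
      if (any(hits)) present <- present + 1L
      if (all(hits)) conserved <- conserved + 1L
    }
  }
  if (present == 0L) 0 else conserved / present
}
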