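#' NODF nestedness of a binary bipartite matrix
#'
#' Computes NODF (nestedness based on overlap and decreasing fill) in its
#' order-invariant pairwise form.  For every unordered pair of rows (and of
#' columns) with degrees \eqn{d_i \ne d_j}, the pair contributes
#' \eqn{100 \, o_{ij} / \min(d_i, d_j)}, where \eqn{o_{ij}} is the number of
#' shared links; pairs with equal degrees contribute 0 ("decreasing fill").
#' NODF is the sum of all pair terms divided by
#' \eqn{\binom{m}{2} + \binom{n}{2}} and lies in \[0, 100\].  This is
#' equivalent to the usual definition on a matrix pre-sorted by decreasing
#' marginal totals, and is therefore invariant under row/column permutation
#' and under transposition.
#'
#' @param mat interaction matrix (counts are binarized, see
#'   [as_interaction_matrix()]).  At least one dimension must exceed 1,
#'   otherwise no pairs exist and the metric is undefined.
#' @return an object of class `"nodf_breakdown"`: a list with
#'   `row_component` and `col_component` (raw sums of pair terms),
#'   `n_pairs`, and `total` (the NODF score).
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))  # perfect staircase: 100
#' nodf(matrix(1, 3, 3))                            # equal degrees: 0
#' @seealso [nodf_total()], [nodf_state()] for incremental evaluation.
#' @export
nodf <- function(mat) {
  mat <- as_interaction_matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  if (m < 2 && n < 2)
    nm_error("NODF is undefined for a matrix with no row or column pairs",
             "nestmax_undefined_metric")
  row_component <- pair_term_sum(rowSums(mat), tcrossprod(mat))
  col_component <- pair_term_sum(colSums(mat), crossprod(mat))
  n_pairs <- choose(m, 2) + choose(n, 2)
  structure(list(row_component = row_component,
                 col_component = col_component,
                 n_pairs = n_pairs,
                 total = (row_component + col_component) / n_pairs),
            class = "nodf_breakdown")
}

# sum of pair terms for one side, given degrees and the overlap matrix
pair_term_sum <- function(deg, O) {
  k <- length(deg)
  if (k < 2) return(0)
  ut <- upper.tri(O)
  di <- deg[row(O)[ut]]
  dj <- deg[col(O)[ut]]
  o <- O[ut]
  lo <- pmin(di, dj)
  ok <- di != dj & lo > 0
  sum(100 * o[ok] / lo[ok])
}

#' @rdname nodf
#' @return `nodf_total()` returns the NODF score as a bare number.
#' @export
nodf_total <- function(mat) nodf(mat)$total

#' @export
print.nodf_breakdown <- function(x, digits = 4, ...) {
  cat(sprintf("NODF: %s (row pair sum %s, column pair sum %s over %d pairs)\n",
              format(x$total, digits = digits),
              format(x$row_component, digits = digits),
              format(x$col_component, digits = digits),
              x$n_pairs))
  invisible(x)
}
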