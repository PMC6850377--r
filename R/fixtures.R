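#' Random feasible matrix of a given shape
#'
#' Draws a binary matrix with the requested numbers of rows, columns and
#' links in which every row and column has at least one link.
#' Construction: a random covering first (each line on the longer side gets
#' exactly one link, a random permutation guaranteeing the shorter side is
#' fully covered), then the remaining links fall uniformly at random on
#' empty cells.  This yields a valid feasible matrix for every feasible
#' shape; it is not claimed to be uniform over all feasible matrices.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @param seed optional integer seed; when `NULL` the current R RNG stream
#'   is used (so callers such as [simulated_annealing()] stay reproducible
#'   under their own seed).
#' @return an integer 0/1 matrix.
#' @examples
#' random_feasible_matrix(network_shape(4, 5, 9), seed = 1)
#' @export
random_feasible_matrix <- function(shape, seed = NULL) {
  shape <- as_network_shape(shape)
  if (!is.null(seed)) set.seed(seed)
  m <- shape$n_rows; n <- shape$n_cols; L <- shape$n_links
  M <- matrix(0L, m, n)
  if (n >= m) {
    cols <- sample.int(n)            # order in which columns are covered
    rows <- c(sample.int(m), if (n > m) sample.int(m, n - m, replace = TRUE))
    M[cbind(rows, cols)] <- 1L
  } else {
    rows <- sample.int(m)
    cols <- c(sample.int(n), sample.int(n, m - n, replace = TRUE))
    M[cbind(rows, cols)] <- 1L
  }
  extra <- L - max(m, n)
  if (extra > 0) {
    empty <- which(M == 0L)
    M[empty[sample.int(length(empty), extra)]] <- 1L
  }
  M
}

#' Perfectly nested staircase matrix (NODF = 100)
#'
#' A matrix scores NODF = 100 exactly when it is fully nested and all row
#' degrees are pairwise distinct and all column degrees are pairwise
#' distinct.  A nested matrix's column degrees are determined by its row
#' degrees (column j is hit by the rows of degree >= j), so distinctness on
#' both sides forces the row degrees to be exactly `n, n-1, ..., 1` on a
#' square `n x n` matrix: the only admissible shapes are
#' `(k, k, k(k+1)/2)` with `k >= 2`.
#'
#' @param n_rows,n_cols,n_links requested shape.
#' @return the left-aligned staircase matrix.
#' @examples
#' perfect_staircase(3, 3, 6)
#' @export
perfect_staircase <- function(n_rows, n_cols, n_links) {
  shape <- network_shape(n_rows, n_cols, n_links)
  k <- shape$n_rows
  if (shape$n_cols != k || k < 2 || shape$n_links != k * (k + 1) / 2)
    nm_error(sprintf(
      "no perfectly nested matrix with distinct degrees exists for %d x %d with %d links (need k x k with k(k+1)/2 links)",
      shape$n_rows, shape$n_cols, shape$n_links),
      "nestmax_infeasible_shape")
  M <- matrix(0L, k, k)
  for (i in seq_len(k)) M[i, seq_len(k - i + 1)] <- 1L
  M
}

#' Enumerate every feasible matrix of a shape
#'
#' Yields each binary matrix with the given shape and link count in which
#' no row or column is empty, exactly once (up to cell-set identity).  The
#' number of candidate placements `choose(rows*cols, links)` must not
#' exceed `cap`; larger shapes are refused, never silently truncated.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @param cap maximum number of candidate placements.
#' @return a list of integer 0/1 matrices.
#' @examples
#' length(enumerate_feasible(network_shape(2, 2, 3)))  # 4
#' @export
enumerate_feasible <- function(shape, cap = 5e6) {
  shape <- as_network_shape(shape)
  m <- shape$n_rows; n <- shape$n_cols; L <- shape$n_links
  ncand <- choose(m * n, L)
  if (ncand > cap)
    nm_error(sprintf(
      "enumeration cap exceeded: choose(%d, %d) = %s candidates > cap %s",
      m * n, L, format(ncand, big.mark = ","), format(cap, big.mark = ",")),
      "nestmax_enumeration_cap")
  out <- combn(m * n, L, FUN = function(cells) {
    r <- ((cells - 1L) %% m) + 1L
    co <- ((cells - 1L) %/% m) + 1L
    if (length(unique(r)) < m || length(unique(co)) < n) return(NULL)
    M <- matrix(0L, m, n)
    M[cells] <- 1L
    M
  }, simplify = FALSE)
  out[!vapply(out, is.null, logical(1))]
}
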