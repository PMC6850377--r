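#' Incremental NODF state
#'
#' Caches degrees and pairwise shared-link counts so that the NODF change
#' from moving a single link can be computed in O(rows + cols) instead of
#' rescoring every pair.  This is what makes simulated annealing over
#' single-link moves cheap: a move touches at most two rows and two
#' columns, so only pair terms involving those lines change.
#'
#' @param mat interaction matrix.
#' @return an object of class `"nodf_state"`: a list with the matrix,
#'   `row_degrees`, `col_degrees`, `row_overlaps`, `col_overlaps`,
#'   `pair_sum`, `n_pairs` and `current_total` (the cached NODF).
#' @seealso [apply_move()], [nodf()]
#' @export
nodf_state <- function(mat) {
  mat <- as_interaction_matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  if (m < 2 && n < 2)
    nm_error("NODF is undefined for a matrix with no row or column pairs",
             "nestmax_undefined_metric")
  rs <- rowSums(mat); cs <- colSums(mat)
  Or <- tcrossprod(mat); Oc <- crossprod(mat)
  ps <- pair_term_sum(rs, Or) + pair_term_sum(cs, Oc)
  np <- choose(m, 2) + choose(n, 2)
  structure(list(matrix = mat,
                 row_degrees = rs, col_degrees = cs,
                 row_overlaps = Or, col_overlaps = Oc,
                 pair_sum = ps, n_pairs = np,
                 current_total = ps / np),
            class = "nodf_state")
}

# sum of pair terms involving lines in `idx` (1 or 2 indices)
sum_involving <- function(deg, O, idx) {
  idx <- unique(idx)
  s <- 0
  others <- seq_along(deg)[-idx[1]]
  s <- s + term_vec(deg[others], deg[idx[1]], O[others, idx[1]])
  if (length(idx) == 2) {
    others <- seq_along(deg)[-idx]
    s <- s + term_vec(deg[others], deg[idx[2]], O[others, idx[2]])
  }
  s
}

term_vec <- function(di, dj, o) {
  lo <- pmin(di, dj)
  ok <- di != dj & lo > 0
  sum(100 * o[ok] / lo[ok])
}

#' Move a single link, updating the cached NODF incrementally
#'
#' Applies the move "remove the link at `remove`, add a link at `add`" to an
#' incremental NODF state.  The move is legal only if the source cell holds
#' a 1, the target cell holds a 0, and the removal does not empty any row or
#' column (so the matrix stays feasible).  Illegal moves raise an
#' `nestmax_invalid_move` error and leave the state untouched.
#'
#' @param state an [nodf_state()].
#' @param remove,add integer `(row, col)` coordinates.
#' @return the updated state.
#' @examples
#' st <- nodf_state(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0)))
#' st2 <- apply_move(st, remove = c(2, 3), add = c(1, 3))
#' st2$current_total
#' @export
apply_move <- function(state, remove, add) {
  stopifnot(inherits(state, "nodf_state"))
  r1 <- as.integer(remove[1]); c1 <- as.integer(remove[2])
  r2 <- as.integer(add[1]);    c2 <- as.integer(add[2])
  M <- state$matrix
  m <- nrow(M); n <- ncol(M)
  if (r1 < 1 || r1 > m || c1 < 1 || c1 > n || r2 < 1 || r2 > m ||
      c2 < 1 || c2 > n)
    nm_error("move coordinates out of bounds", "nestmax_invalid_move")
  if (M[r1, c1] != 1L)
    nm_error("source cell holds no link", "nestmax_invalid_move")
  if (M[r2, c2] != 0L)
    nm_error("target cell is already occupied", "nestmax_invalid_move")
  if (state$row_degrees[r1] <= 1L || state$col_degrees[c1] <= 1L)
    nm_error("removal would empty a row or column (infeasible)",
             "nestmax_invalid_move")

  rs <- state$row_degrees; cs <- state$col_degrees
  Or <- state$row_overlaps; Oc <- state$col_overlaps
  rows <- c(r1, r2); cols <- c(c1, c2)
  before <- sum_involving(rs, Or, rows) + sum_involving(cs, Oc, cols)

  # remove (r1, c1)
  M[r1, c1] <- 0L; rs[r1] <- rs[r1] - 1L; cs[c1] <- cs[c1] - 1L
  v <- M[, c1]
  Or[, r1] <- Or[, r1] - v; Or[r1, ] <- Or[r1, ] - v; Or[r1, r1] <- rs[r1]
  w <- M[r1, ]
  Oc[, c1] <- Oc[, c1] - w; Oc[c1, ] <- Oc[c1, ] - w; Oc[c1, c1] <- cs[c1]
  # add (r2, c2)
  M[r2, c2] <- 1L; rs[r2] <- rs[r2] + 1L; cs[c2] <- cs[c2] + 1L
  v <- M[, c2]
  Or[, r2] <- Or[, r2] + v; Or[r2, ] <- Or[r2, ] + v; Or[r2, r2] <- rs[r2]
  w <- M[r2, ]
  Oc[, c2] <- Oc[, c2] + w; Oc[c2, ] <- Oc[c2, ] + w; Oc[c2, c2] <- cs[c2]

  after <- sum_involving(rs, Or, rows) + sum_involving(cs, Oc, cols)
  state$matrix <- M
  state$row_degrees <- rs; state$col_degrees <- cs
  state$row_overlaps <- Or; state$col_overlaps <- Oc
  state$pair_sum <- state$pair_sum + (after - before)
  state$current_total <- state$pair_sum / state$n_pairs
  state
}

#' @export
print.nodf_state <- function(x, ...) {
  cat(sprintf("incremental NODF state: %d x %d, %d links, NODF %.4f\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix), x$current_total))
  invisible(x)
}
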