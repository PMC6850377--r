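#' Coerce to a binary interaction matrix
#'
#' Validates and binarizes a bipartite interaction matrix.  Rows are one
#' guild (conventionally plants), columns the other (pollinators).  Any
#' strictly positive cell value (e.g. a visitation count) becomes a 1;
#' zeros stay 0.  Negative or missing cells are input errors.
#'
#' @param x a numeric matrix or data frame of nonnegative counts or 0/1
#'   presences.
#' @return an integer 0/1 matrix, dimnames preserved.
#' @examples
#' as_interaction_matrix(rbind(c(3, 0), c(1, 2)))
#' @export
as_interaction_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) nm_error("input must be a matrix", "nestmax_input_error")
  if (!is.numeric(x)) nm_error("matrix cells must be numeric", "nestmax_input_error")
  if (anyNA(x)) nm_error("matrix contains missing values", "nestmax_input_error")
  if (any(x < 0)) nm_error("matrix contains negative values", "nestmax_input_error")
  out <- matrix(as.integer(x > 0), nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Check interaction-matrix invariants
#'
#' @param mat a 0/1 matrix (see [as_interaction_matrix()]).
#' @param require_feasible if `TRUE`, every row and column must have at
#'   least one link (the feasibility constraint used during maximization).
#' @return `mat`, invisibly.
#' @export
validate_matrix <- function(mat, require_feasible = FALSE) {
  mat <- as_interaction_matrix(mat)
  if (require_feasible && (any(rowSums(mat) == 0) || any(colSums(mat) == 0)))
    nm_error("matrix is infeasible: some row or column has no link",
             "nestmax_infeasible_matrix")
  invisible(mat)
}

#' Network shape (rows, columns, links)
#'
#' A shape is feasible when `max(n_rows, n_cols) <= n_links <= n_rows * n_cols`,
#' i.e. when at least one binary matrix of that size and fill exists in which
#' every row and column has at least one link.
#'
#' @param n_rows,n_cols,n_links positive integers.
#' @return an object of class `"network_shape"`.
#' @examples
#' network_shape(3, 4, 6)
#' @export
network_shape <- function(n_rows, n_cols, n_links) {
  v <- c(n_rows, n_cols, n_links)
  if (length(v) != 3 || anyNA(v) || any(v != round(v)) || any(v < 1))
    nm_error("n_rows, n_cols, n_links must be positive integers",
             "nestmax_infeasible_shape")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_links <- as.integer(n_links)
  if (n_links < max(n_rows, n_cols) || n_links > n_rows * n_cols)
    nm_error(sprintf(
      "infeasible shape: need max(%d, %d) <= links <= %d, got %d",
      n_rows, n_cols, n_rows * n_cols, n_links), "nestmax_infeasible_shape")
  structure(list(n_rows = n_rows, n_cols = n_cols, n_links = n_links),
            class = "network_shape")
}

as_network_shape <- function(shape) {
  if (inherits(shape, "network_shape")) return(shape)
  if (is.numeric(shape) && length(shape) == 3)
    return(network_shape(shape[1], shape[2], shape[3]))
  if (is.list(shape) && all(c("n_rows", "n_cols", "n_links") %in% names(shape)))
    return(network_shape(shape$n_rows, shape$n_cols, shape$n_links))
  nm_error("cannot interpret shape; use network_shape()", "nestmax_infeasible_shape")
}

#' @export
print.network_shape <- function(x, ...) {
  cat(sprintf("network shape: %d rows x %d cols, %d links (connectance %.3f)\n",
              x$n_rows, x$n_cols, x$n_links,
              x$n_links / (x$n_rows * x$n_cols)))
  invisible(x)
}

#' Shape of an interaction matrix
#' @param mat a 0/1 matrix.
#' @return a [network_shape()].
#' @export
shape_of <- function(mat) {
  mat <- as_interaction_matrix(mat)
  network_shape(nrow(mat), ncol(mat), sum(mat))
}
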