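#' Normalized nestedness NODF_n
#'
#' The ratio of an observed NODF to the maximum NODF attainable by any
#' feasible matrix with the same shape and link count:
#' `NODF_n = NODF / max(NODF)`.  Both values must be on the same (0-100)
#' scale, so the ratio is scale-free.  When `nodf_max` is a true maximum
#' the ratio lies in \[0, 1\]; an underestimated maximum (e.g. from a
#' greedy heuristic stuck in a local optimum) inflates it.
#'
#' @param nodf_observed observed NODF in \[0, 100\].
#' @param nodf_max maximum NODF for the shape, > 0.
#' @return `nodf_observed / nodf_max`.
#' @export
normalized_nestedness <- function(nodf_observed, nodf_max) {
  if (!is.numeric(nodf_observed) || !is.numeric(nodf_max) ||
      anyNA(nodf_observed) || anyNA(nodf_max))
    nm_error("NODF values must be numeric", "nestmax_input_error")
  if (any(nodf_max <= 0))
    nm_error("nodf_max must be positive to normalize", "nestmax_undefined_normalization")
  if (any(nodf_observed < 0))
    nm_error("nodf_observed must be nonnegative", "nestmax_input_error")
  nodf_observed / nodf_max
}

#' Connectance of a matrix or shape
#' @param x an interaction matrix or [network_shape()].
#' @return realized links divided by possible links (rows * cols).
#' @export
connectance <- function(x) {
  s <- if (inherits(x, "network_shape")) x else shape_of(x)
  s$n_links / (s$n_rows * s$n_cols)
}

#' Network size S (geometric mean of guild sizes)
#' @param x an interaction matrix or [network_shape()].
#' @return `sqrt(rows * cols)`.
#' @export
network_size <- function(x) {
  s <- if (inherits(x, "network_shape")) x else shape_of(x)
  sqrt(s$n_rows * s$n_cols)
}

#' Combined nestedness statistic NODF_c
#'
#' Computes the full normalized summary of an observed matrix:
#' `NODF_n = NODF / max(NODF)` and
#' `NODF_c = NODF_n / (C * log(S))`, where `C` is connectance and `S` the
#' geometric mean of the numbers of rows and columns.  `NODF_c` corrects
#' the normalized nestedness for the residual effects of connectance and
#' network size so that values are comparable across networks.  All
#' ingredients are transpose-invariant, so `NODF_c` is too.
#'
#' @param mat the observed interaction matrix.
#' @param nodf_max the maximum NODF for `mat`'s shape (e.g. from
#'   [simulated_annealing()] or [brute_force_max()]); when `NULL` it is
#'   estimated by simulated annealing with `schedule`.
#' @param schedule an [annealing_schedule()], used only when `nodf_max` is
#'   `NULL`.
#' @param log_base base of the logarithm of S (natural log by default).
#' @return an object of class `"network_summary"`: a list with
#'   `nodf_observed`, `nodf_max`, `nodf_n`, `connectance`, `size` and
#'   `nodf_c`.
#' @examples
#' m <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
#' combined_statistic(m, nodf_max = 100)
#' @export
combined_statistic <- function(mat, nodf_max = NULL,
                               schedule = annealing_schedule(),
                               log_base = exp(1)) {
  mat <- as_interaction_matrix(mat)
  s <- shape_of(mat)
  S <- network_size(s)
  if (S <= 1)
    nm_error("network size S must exceed 1 for NODF_c (log(S) > 0)",
             "nestmax_undefined_normalization")
  obs <- nodf(mat)$total
  if (is.null(nodf_max))
    nodf_max <- simulated_annealing(s, schedule, init = "greedy")$best_nodf
  nodf_n <- normalized_nestedness(obs, nodf_max)
  C <- connectance(s)
  structure(list(n_rows = s$n_rows, n_cols = s$n_cols, n_links = s$n_links,
                 nodf_observed = obs, nodf_max = nodf_max, nodf_n = nodf_n,
                 connectance = C, size = S,
                 nodf_c = nodf_n / (C * log(S, base = log_base))),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, digits = 5, ...) {
  cat(sprintf("network %d x %d, %d links (C = %.4f, S = %.3f)\n",
              x$n_rows, x$n_cols, x$n_links, x$connectance, x$size))
  cat(sprintf("  NODF = %s  max(NODF) = %s\n",
              format(x$nodf_observed, digits = digits),
              format(x$nodf_max, digits = digits)))
  cat(sprintf("  NODF_n = %s  NODF_c = %s\n",
              format(x$nodf_n, digits = digits),
              format(x$nodf_c, digits = digits)))
  invisible(x)
}
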