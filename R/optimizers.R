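#' Annealing schedule
#'
#' Parameters of the geometric cooling schedule used by
#' [simulated_annealing()].  Defaults: `t0 = NULL` auto-calibrates the
#' starting temperature so that roughly 80% of uphill-cost moves from the
#' starting matrix would be accepted (estimated from the mean uphill cost
#' change of 100 sampled moves); `t_min = NULL` becomes `t0 * 1e-4`;
#' `n_per_temp = NULL` becomes `10 * n_links` moves per temperature level.
#'
#' @param t0 starting temperature (> 0), or `NULL` to calibrate.
#' @param t_min termination temperature (0 < `t_min` < `t0`), or `NULL`.
#' @param alpha geometric cooling rate, strictly between 0 and 1.
#' @param n_per_temp moves attempted per temperature level, or `NULL`.
#' @param seed integer RNG seed; the same seed, schedule and shape give a
#'   bit-identical result.
#' @param accept_target target initial uphill acceptance rate used by the
#'   `t0` calibration.
#' @return an object of class `"annealing_schedule"`.
#' @export
annealing_schedule <- function(t0 = NULL, t_min = NULL, alpha = 0.95,
                               n_per_temp = NULL, seed = 1L,
                               accept_target = 0.8) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    nm_error("alpha must lie strictly between 0 and 1", "nestmax_invalid_schedule")
  if (!is.null(t0) && (!is.numeric(t0) || t0 <= 0))
    nm_error("t0 must be positive", "nestmax_invalid_schedule")
  if (!is.null(t_min)) {
    if (!is.numeric(t_min) || t_min <= 0)
      nm_error("t_min must be positive", "nestmax_invalid_schedule")
    if (!is.null(t0) && t_min >= t0)
      nm_error("t_min must be smaller than t0", "nestmax_invalid_schedule")
  }
  if (!is.null(n_per_temp) && (n_per_temp < 1 || n_per_temp != round(n_per_temp)))
    nm_error("n_per_temp must be a positive integer", "nestmax_invalid_schedule")
  if (accept_target <= 0 || accept_target >= 1)
    nm_error("accept_target must lie strictly between 0 and 1",
             "nestmax_invalid_schedule")
  structure(list(t0 = t0, t_min = t_min, alpha = alpha,
                 n_per_temp = if (is.null(n_per_temp)) NULL else as.integer(n_per_temp),
                 seed = as.integer(seed), accept_target = accept_target),
            class = "annealing_schedule")
}

#' Metropolis/Kirkpatrick acceptance probability
#'
#' Probability of accepting a neighbour with cost `cost_prime` from a state
#' with cost `cost` at temperature `temperature`:
#' 1 when `cost_prime <= cost`, otherwise
#' `exp((cost - cost_prime) / temperature)`.  Costs are `1 - NODF/100`.
#'
#' @param cost,cost_prime current and neighbour costs.
#' @param temperature positive temperature.
#' @return acceptance probability in \[0, 1\] (vectorized).
#' @examples
#' acceptance_probability(0.5, 0.6, 0.1)  # exp(-1)
#' @export
acceptance_probability <- function(cost, cost_prime, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    nm_error("temperature must be positive", "nestmax_invalid_schedule")
  pmin(1, exp((cost - cost_prime) / temperature))
}

#' Propose a random single-link move
#'
#' Neighbours of a feasible matrix are the feasible matrices reachable by
#' moving one link to an empty cell.  The proposal removes a uniformly
#' random link whose removal keeps every row and column occupied, and adds
#' it at a uniformly random empty cell; every legal move has positive
#' probability.  Uses the current R RNG stream.
#'
#' @param mat a feasible interaction matrix.
#' @return a list with `remove` and `add`, each a `(row, col)` pair.
#' @export
propose_move <- function(mat) {
  mat <- validate_matrix(mat, require_feasible = TRUE)
  rs <- rowSums(mat); cs <- colSums(mat)
  removable <- which(mat == 1L & rs[row(mat)] > 1L & cs[col(mat)] > 1L)
  empty <- which(mat == 0L)
  if (length(removable) == 0 || length(empty) == 0)
    nm_error("no legal single-link move exists for this matrix",
             "nestmax_exhausted_neighborhood")
  a <- removable[sample.int(length(removable), 1L)]
  b <- empty[sample.int(length(empty), 1L)]
  m <- nrow(mat)
  list(remove = c(((a - 1L) %% m) + 1L, ((a - 1L) %/% m) + 1L),
       add    = c(((b - 1L) %% m) + 1L, ((b - 1L) %/% m) + 1L))
}

new_opt_result <- function(best_matrix, best_nodf, evaluations, algorithm,
                           seed = NA_integer_, trajectory = NULL,
                           schedule = NULL) {
  structure(list(best_matrix = best_matrix, best_nodf = best_nodf,
                 evaluations = evaluations, algorithm = algorithm,
                 seed = seed, trajectory = trajectory, schedule = schedule),
            class = "nodf_opt")
}

#' @export
print.nodf_opt <- function(x, ...) {
  cat(sprintf("%s: best NODF %.6f (%d x %d, %d links; %s NODF evaluations)\n",
              x$algorithm, x$best_nodf, nrow(x$best_matrix),
              ncol(x$best_matrix), sum(x$best_matrix),
              format(x$evaluations, big.mark = ",")))
  invisible(x)
}

#' Greedy NODF maximization
#'
#' Builds a matrix of the requested shape by adding links one at a time,
#' each at the empty position giving the largest NODF increase (first in
#' row-major order on ties).  Placement is restricted so that full
#' row/column coverage stays achievable with the links remaining, which
#' guarantees a feasible result for every feasible shape.  Deterministic.
#' Greedy placement is a local heuristic: it can (and often does) end in a
#' local optimum below the true maximum.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @return an optimization result (class `"nodf_opt"`).
#' @examples
#' greedy_maximize(network_shape(2, 2, 3))$best_nodf  # 100
#' @export
greedy_maximize <- function(shape) {
  shape <- as_network_shape(shape)
  res <- .greedy_max_cpp(shape$n_rows, shape$n_cols, shape$n_links)
  new_opt_result(res$matrix, res$nodf, res$evaluations, "greedy")
}

#' Simulated annealing NODF maximization
#'
#' Classical simulated annealing over single-link moves.  Starts from a
#' random feasible matrix (or a greedy-seeded one), proposes a random
#' neighbour per iteration, accepts it with the Metropolis/Kirkpatrick
#' probability [acceptance_probability()] on the cost `1 - NODF/100`, runs
#' `n_per_temp` iterations per temperature level, multiplies the
#' temperature by `alpha` after each level, stops below `t_min`, and
#' returns the best matrix observed anywhere along the run (not merely the
#' final state).  NODF is re-evaluated incrementally per move.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @param schedule an [annealing_schedule()].
#' @param init `"random"` (the default) or `"greedy"`; with `"greedy"` the
#'   run starts from [greedy_maximize()]'s matrix, so the result can never
#'   fall below the greedy score.
#' @param init_matrix optional explicit feasible starting matrix of the
#'   requested shape (overrides `init`).
#' @return an optimization result (class `"nodf_opt"`) with a
#'   per-temperature trajectory (`temperature`, `best_nodf`,
#'   `acceptance_rate`) and the resolved schedule.
#' @examples
#' simulated_annealing(network_shape(3, 3, 6),
#'                     annealing_schedule(seed = 42))$best_nodf
#' @export
simulated_annealing <- function(shape, schedule = annealing_schedule(),
                                init = c("random", "greedy"),
                                init_matrix = NULL) {
  shape <- as_network_shape(shape)
  if (!inherits(schedule, "annealing_schedule"))
    nm_error("schedule must be an annealing_schedule()", "nestmax_invalid_schedule")
  init <- match.arg(init)
  if (shape$n_rows < 2 && shape$n_cols < 2)
    nm_error("NODF is undefined for a 1 x 1 network", "nestmax_undefined_metric")

  set.seed(schedule$seed)
  if (!is.null(init_matrix)) {
    start <- validate_matrix(init_matrix, require_feasible = TRUE)
    if (nrow(start) != shape$n_rows || ncol(start) != shape$n_cols ||
        sum(start) != shape$n_links)
      nm_error("init_matrix does not match the requested shape",
               "nestmax_infeasible_shape")
  } else if (init == "greedy") {
    start <- greedy_maximize(shape)$best_matrix
  } else {
    start <- random_feasible_matrix(shape)
  }

  n_per_temp <- schedule$n_per_temp
  if (is.null(n_per_temp)) n_per_temp <- max(1L, 10L * shape$n_links)
  res <- .sa_cpp(start,
                 if (is.null(schedule$t0)) NA_real_ else schedule$t0,
                 if (is.null(schedule$t_min)) NA_real_ else schedule$t_min,
                 schedule$alpha, n_per_temp, schedule$accept_target, TRUE)
  resolved <- schedule
  resolved$t0 <- res$t0
  resolved$t_min <- res$t_min
  resolved$n_per_temp <- n_per_temp
  new_opt_result(res$best_matrix, res$best_nodf, res$evaluations, "anneal",
                 seed = schedule$seed, trajectory = res$trajectory,
                 schedule = resolved)
}

#' Exact maximum NODF by exhaustive enumeration
#'
#' Enumerates every feasible matrix of the given shape (see
#' [enumerate_feasible()]) and returns the global maximum NODF with one
#' maximizing matrix.  Refuses shapes whose candidate count
#' `choose(rows*cols, links)` exceeds `cap` rather than silently
#' approximating.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @param cap maximum number of candidate link placements to enumerate.
#' @return an optimization result (class `"nodf_opt"`); `evaluations` is
#'   the number of feasible matrices scored.
#' @examples
#' brute_force_max(network_shape(3, 3, 6))$best_nodf  # 100
#' @export
brute_force_max <- function(shape, cap = 5e6) {
  shape <- as_network_shape(shape)
  if (shape$n_rows < 2 && shape$n_cols < 2)
    nm_error("NODF is undefined for a 1 x 1 network", "nestmax_undefined_metric")
  m <- shape$n_rows; n <- shape$n_cols; L <- shape$n_links
  ncand <- choose(m * n, L)
  if (ncand > cap)
    nm_error(sprintf(
      "enumeration cap exceeded: choose(%d, %d) = %s candidates > cap %s",
      m * n, L, format(ncand, big.mark = ","), format(cap, big.mark = ",")),
      "nestmax_enumeration_cap")
  np <- choose(m, 2) + choose(n, 2)
  best <- -Inf; best_cells <- NULL; n_feasible <- 0L
  score_one <- function(cells) {
    r <- ((cells - 1L) %% m) + 1L
    co <- ((cells - 1L) %/% m) + 1L
    if (length(unique(r)) < m || length(unique(co)) < n) return(invisible(NULL))
    n_feasible <<- n_feasible + 1L
    M <- matrix(0L, m, n)
    M[cells] <- 1L
    s <- (pair_term_sum(rowSums(M), tcrossprod(M)) +
          pair_term_sum(colSums(M), crossprod(M))) / np
    if (s > best) { best <<- s; best_cells <<- cells }
    invisible(NULL)
  }
  invisible(combn(m * n, L, FUN = score_one, simplify = FALSE))
  if (!is.finite(best))
    nm_error("no feasible matrix exists for this shape", "nestmax_infeasible_shape")
  M <- matrix(0L, m, n)
  M[best_cells] <- 1L
  new_opt_result(M, best, n_feasible, "brute")
}

#' Compare simulated annealing with the greedy heuristic
#'
#' Runs [greedy_maximize()] and [simulated_annealing()] on the same shape
#' and reports the percentage change
#' `100 * (sa_best - greedy_best) / greedy_best`.  By default the annealer
#' is seeded with the greedy matrix, so (best-so-far tracking starting at
#' the seed) the change is never negative: annealing can only match or
#' improve on greedy.
#'
#' @param shape a [network_shape()] or `c(rows, cols, links)`.
#' @param schedule an [annealing_schedule()].
#' @param sa_init starting policy for the annealer; `"greedy"` (default)
#'   guarantees a non-negative percentage change.
#' @return a list of class `"greedy_comparison"` with `greedy_nodf`,
#'   `sa_nodf` and `pct_change` (`NA` with a warning when greedy scores 0
#'   but annealing does not, which only degenerate shapes can produce).
#' @export
compare_to_greedy <- function(shape, schedule = annealing_schedule(),
                              sa_init = c("greedy", "random")) {
  shape <- as_network_shape(shape)
  sa_init <- match.arg(sa_init)
  g <- greedy_maximize(shape)
  sa <- simulated_annealing(shape, schedule, init = sa_init)
  if (g$best_nodf > 0) {
    pct <- 100 * (sa$best_nodf - g$best_nodf) / g$best_nodf
  } else if (sa$best_nodf == 0) {
    pct <- 0
  } else {
    nm_warning("greedy maximum is 0; percentage change undefined",
               "nestmax_undefined_percentage")
    pct <- NA_real_
  }
  structure(list(shape = shape, greedy_nodf = g$best_nodf,
                 sa_nodf = sa$best_nodf, pct_change = pct,
                 seed = schedule$seed, sa_init = sa_init),
            class = "greedy_comparison")
}

#' @export
print.greedy_comparison <- function(x, ...) {
  cat(sprintf(
    "greedy %.6f vs annealing %.6f: %s%% change (%d x %d, %d links)\n",
    x$greedy_nodf, x$sa_nodf,
    if (is.na(x$pct_change)) "undefined" else sprintf("%+.3f", x$pct_change),
    x$shape$n_rows, x$shape$n_cols, x$shape$n_links))
  invisible(x)
}
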