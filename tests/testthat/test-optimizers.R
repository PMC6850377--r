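test_that("greedy returns feasible matrices of the exact requested fill", {
  set.seed(3)
  for (i in 1:10) {
    s <- random_shape(3, 10, 0.15, 0.6)
    r <- greedy_maximize(s)
    expect_feasible(r$best_matrix, s)
    expect_equal(r$best_nodf, nodf_total(r$best_matrix), tolerance = 1e-9)
  }
  # includes shapes below the row-1/column-1 backbone size m + n - 1
  r <- greedy_maximize(network_shape(3, 4, 4))
  expect_feasible(r$best_matrix, network_shape(3, 4, 4))
})

test_that("greedy anchors and determinism", {
  expect_equal(greedy_maximize(c(3, 3, 9))$best_nodf, 0)
  expect_equal(greedy_maximize(c(2, 2, 3))$best_nodf, 100)
  a <- greedy_maximize(c(7, 9, 22)); b <- greedy_maximize(c(7, 9, 22))
  expect_identical(a$best_matrix, b$best_matrix)
  expect_error(greedy_maximize(c(3, 3, 2)), class = "nestmax_infeasible_shape")
})

test_that("acceptance probability follows the Kirkpatrick form", {
  expect_equal(acceptance_probability(0.5, 0.4, 0.1), 1)
  expect_equal(acceptance_probability(0.5, 0.5, 1e-6), 1)
  expect_equal(acceptance_probability(0.5, 0.6, 0.1), exp(-1))
  expect_equal(acceptance_probability(0.3, 0.7, 2), exp(-0.2))
  # monotone in temperature for a fixed uphill step
  p <- acceptance_probability(0.2, 0.4, c(0.01, 0.1, 1, 10, 1e6))
  expect_true(all(diff(p) > 0))
  expect_lt(p[1], 1e-8)
  expect_gt(p[5], 1 - 1e-6)
  expect_error(acceptance_probability(0.1, 0.2, 0), class = "nestmax_invalid_schedule")
})

test_that("proposed moves are legal and cover the whole legal neighbourhood", {
  M <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  # enumerate legal moves by brute force
  rs <- rowSums(M); cs <- colSums(M)
  legal <- list()
  for (a in which(M == 1L)) {
    r1 <- (a - 1L) %% 3L + 1L; c1 <- (a - 1L) %/% 3L + 1L
    if (rs[r1] <= 1L || cs[c1] <= 1L) next
    for (b in which(M == 0L)) legal[[length(legal) + 1L]] <- c(a, b)
  }
  key <- function(ab) paste(ab, collapse = "-")
  want <- sort(vapply(legal, key, character(1)))
  set.seed(5)
  seen <- character(0)
  for (i in 1:5000) {
    mv <- propose_move(M)
    a <- mv$remove[1] + 3L * (mv$remove[2] - 1L)
    b <- mv$add[1] + 3L * (mv$add[2] - 1L)
    expect_true(key(c(a, b)) %in% want)
    seen <- c(seen, key(c(a, b)))
  }
  expect_identical(sort(unique(seen)), want)
})

test_that("exhausted neighbourhoods are signalled", {
  expect_error(propose_move(matrix(1L, 3, 3)),
               class = "nestmax_exhausted_neighborhood")
  expect_error(propose_move(diag(2)),
               class = "nestmax_exhausted_neighborhood")
})

test_that("brute force finds exact optima on enumerable shapes", {
  expect_equal(brute_force_max(c(2, 2, 4))$best_nodf, 0)
  r <- brute_force_max(c(2, 2, 3))
  expect_equal(r$best_nodf, 100)
  expect_equal(r$evaluations, 4)  # all C(4,3) fills are feasible
  expect_equal(brute_force_max(c(3, 3, 6))$best_nodf, 100)
  expect_error(brute_force_max(c(10, 10, 50), cap = 1000),
               class = "nestmax_enumeration_cap")
})

test_that("annealing anchors: forced and trivially solvable shapes", {
  expect_equal(simulated_annealing(c(3, 3, 9))$best_nodf, 0)
  expect_equal(simulated_annealing(c(2, 2, 3))$best_nodf, 100)
  # L = max(m, n): every feasible matrix scores 0, SA must return it
  expect_equal(simulated_annealing(c(5, 5, 5))$best_nodf, 0)
})

test_that("annealing is reproducible and its best-so-far is monotone", {
  sch <- annealing_schedule(seed = 99)
  a <- simulated_annealing(c(5, 7, 14), sch)
  b <- simulated_annealing(c(5, 7, 14), sch)
  expect_identical(a$best_matrix, b$best_matrix)
  expect_identical(a$best_nodf, b$best_nodf)
  expect_identical(a$trajectory, b$trajectory)
  expect_true(all(diff(a$trajectory$best_nodf) >= 0))
  expect_true(all(diff(a$trajectory$temperature) < 0))
  expect_equal(a$best_nodf, nodf_total(a$best_matrix), tolerance = 1e-9)
  expect_feasible(a$best_matrix, network_shape(5, 7, 14))
})

test_that("annealing finds the known optimum on (3,3,6) across seeds", {
  hits <- 0
  for (seed in 1:20) {
    r <- simulated_annealing(c(3, 3, 6), annealing_schedule(seed = seed))
    expect_lte(r$best_nodf, 100 + 1e-9)
    hits <- hits + (r$best_nodf >= 100 - 1e-9)
  }
  expect_gte(hits, 19)
})

test_that("schedule validation rejects nonsense parameters", {
  expect_error(annealing_schedule(alpha = 1), class = "nestmax_invalid_schedule")
  expect_error(annealing_schedule(alpha = 0), class = "nestmax_invalid_schedule")
  expect_error(annealing_schedule(t0 = -1), class = "nestmax_invalid_schedule")
  expect_error(annealing_schedule(t0 = 1, t_min = 2),
               class = "nestmax_invalid_schedule")
  expect_error(simulated_annealing(c(3, 3, 2)), class = "nestmax_infeasible_shape")
})

test_that("greedy-seeded annealing never scores below greedy", {
  set.seed(23)
  for (i in 1:8) {
    s <- random_shape(4, 10, 0.15, 0.5)
    cmp <- compare_to_greedy(s, annealing_schedule(seed = i))
    expect_gte(cmp$pct_change, 0)
    expect_gte(cmp$sa_nodf, cmp$greedy_nodf)
  }
  expect_equal(compare_to_greedy(c(3, 3, 9))$pct_change, 0)
  expect_equal(compare_to_greedy(c(2, 2, 3))$pct_change, 0)
})
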