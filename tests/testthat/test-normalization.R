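test_that("NODF_n is the exact observed/maximum ratio", {
  expect_equal(normalized_nestedness(30, 60), 0.5)
  expect_equal(normalized_nestedness(42.5, 42.5), 1)
  expect_equal(normalized_nestedness(0, 55), 0)
  expect_error(normalized_nestedness(10, 0),
               class = "nestmax_undefined_normalization")
  expect_error(normalized_nestedness(-1, 10), class = "nestmax_input_error")
})

test_that("connectance and size follow their definitions", {
  M <- matrix(0L, 5, 8); M[cbind(rep(1:5, 4), rep(1:4, each = 5))] <- 1L
  expect_equal(connectance(M), 20 / 40)
  expect_equal(network_size(network_shape(4, 9, 12)), 6)
  expect_equal(connectance(network_shape(4, 9, 12)), 12 / 36)
})

test_that("NODF_c recomputes from its printed formula", {
  # nodf_n = 0.5, C = 0.25, S = 10 -> 0.5 / (0.25 * ln 10)
  expect_equal(0.5 / (0.25 * log(10)), 0.8685889638, tolerance = 1e-9)
  s <- combined_statistic(staircase3, nodf_max = 100)
  expect_equal(s$nodf_n, 1)
  expect_equal(s$size, 3)
  expect_equal(s$connectance, 6 / 9)
  expect_equal(s$nodf_c, 1 / ((6 / 9) * log(3)))
  # alternative log base is honoured
  s10 <- combined_statistic(staircase3, nodf_max = 100, log_base = 10)
  expect_equal(s10$nodf_c, 1 / ((6 / 9) * log10(3)))
})

test_that("summary fields are mutually consistent on a nontrivial matrix", {
  M <- random_feasible_matrix(network_shape(6, 8, 20), seed = 8)
  s <- combined_statistic(M, nodf_max = nodf_total(M))  # self-normalized
  expect_equal(s$nodf_n, 1)
  s2 <- combined_statistic(M, nodf_max = 2 * nodf_total(M))
  expect_equal(s2$nodf_n, 0.5)
  expect_equal(s2$nodf_c, s2$nodf_n / (s2$connectance * log(s2$size)))
})

test_that("NODF_c is transpose-invariant", {
  set.seed(12)
  for (i in 1:8) {
    M <- random_feasible_matrix(random_shape(3, 9, 0.2, 0.6))
    a <- combined_statistic(M, nodf_max = 90)
    b <- combined_statistic(t(M), nodf_max = 90)
    expect_equal(a$nodf_c, b$nodf_c, tolerance = 1e-12)
    expect_equal(a$connectance, b$connectance)
    expect_equal(a$size, b$size)
  }
})

test_that("an under-estimated maximum inflates NODF_n", {
  # heuristic max <= true max  =>  heuristic-normalized NODF_n >= true NODF_n
  set.seed(4)
  for (i in 1:6) {
    m <- sample(2:3, 1); n <- sample(2:4, 1)
    L <- sample(max(m, n):(m * n), 1)
    s <- network_shape(m, n, L)
    true_max <- brute_force_max(s)$best_nodf
    greedy_max <- greedy_maximize(s)$best_nodf
    if (true_max == 0 || greedy_max == 0) next
    M <- random_feasible_matrix(s)
    obs <- nodf_total(M)
    expect_lte(greedy_max, true_max + 1e-9)
    expect_gte(normalized_nestedness(obs, greedy_max),
               normalized_nestedness(obs, true_max) - 1e-12)
  }
})

test_that("degenerate sizes are refused", {
  expect_error(combined_statistic(matrix(1, 1, 1), nodf_max = 50),
               class = "nestmax_error")
})
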