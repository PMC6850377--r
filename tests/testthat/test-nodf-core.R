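test_that("NODF anchors: staircase, flat, identity, minimal nested", {
  expect_equal(nodf_total(staircase3), 100)
  expect_equal(nodf_total(matrix(1, 3, 3)), 0)
  expect_equal(nodf_total(matrix(1, 4, 7)), 0)
  expect_equal(nodf_total(diag(2)), 0)
  expect_equal(nodf_total(diag(5)), 0)
  expect_equal(nodf_total(rbind(c(1, 1), c(1, 0))), 100)
})

test_that("breakdown components are raw pair sums consistent with the total", {
  b <- nodf(staircase3)
  expect_equal(b$row_component, 300)   # three row pairs, each 100
  expect_equal(b$col_component, 300)
  expect_equal(b$n_pairs, 6)
  expect_equal(b$total, (b$row_component + b$col_component) / b$n_pairs)
})

test_that("NODF matches a naive pair-loop oracle and vegan on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:25) {
    M <- random_feasible_matrix(random_shape(3, 10, 0.2, 0.7))
    ours <- nodf_total(M)
    expect_equal(ours, oracle_nodf(M), tolerance = 1e-12)
    veg <- unname(vegan::nestednodf(M, order = TRUE)$statistic["NODF"])
    expect_equal(ours, veg, tolerance = 1e-10)
  }
})

test_that("NODF is invariant under row/column permutation and transposition", {
  set.seed(7)
  for (i in 1:20) {
    M <- random_feasible_matrix(random_shape(3, 9, 0.2, 0.7))
    P <- M[sample(nrow(M)), sample(ncol(M)), drop = FALSE]
    expect_equal(nodf_total(P), nodf_total(M), tolerance = 1e-12)
    bt <- nodf(t(M)); b <- nodf(M)
    expect_equal(bt$total, b$total, tolerance = 1e-12)
    expect_equal(bt$row_component, b$col_component)
    expect_equal(bt$col_component, b$row_component)
  }
})

test_that("NODF lies in [0, 100] on random feasible matrices", {
  set.seed(11)
  for (i in 1:50) {
    x <- nodf_total(random_feasible_matrix(random_shape(2, 12, 0.1, 0.9)))
    expect_gte(x, 0)
    expect_lte(x, 100)
  }
})

test_that("counts binarize, negatives and NA are rejected, 1x1 is undefined", {
  expect_equal(as_interaction_matrix(rbind(c(7, 0), c(2, 1)))[1, 1], 1L)
  expect_equal(nodf_total(rbind(c(7, 0), c(2, 1))),
               nodf_total(rbind(c(1, 0), c(1, 1))))
  expect_error(nodf(rbind(c(-1, 1), c(1, 1))), class = "nestmax_input_error")
  expect_error(nodf(rbind(c(NA, 1), c(1, 1))), class = "nestmax_input_error")
  expect_error(nodf(matrix(1, 1, 1)), class = "nestmax_undefined_metric")
})

test_that("single-row/column matrices score via the remaining side's pairs", {
  # one row: only column pairs exist
  expect_equal(nodf_total(matrix(c(1, 1, 1), 1, 3)), 0)
  b <- nodf(matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(b$n_pairs, 2)
})
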