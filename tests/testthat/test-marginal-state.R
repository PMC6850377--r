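test_that("fresh state reproduces the from-scratch score", {
  for (M in list(staircase3, matrix(1, 3, 3), diag(3),
                 random_feasible_matrix(network_shape(6, 9, 20), seed = 5))) {
    st <- nodf_state(M)
    expect_equal(st$current_total, nodf_total(M), tolerance = 1e-9)
    expect_equal(st$row_degrees, rowSums(as_interaction_matrix(M)))
    expect_equal(unname(st$col_overlaps), unname(crossprod(as_interaction_matrix(M))))
  }
})

test_that("illegal moves raise invalid-move errors and leave the state intact", {
  st <- nodf_state(diag(2))
  # removing (2,2) would empty row 2 and column 2
  expect_error(apply_move(st, remove = c(2, 2), add = c(2, 1)),
               class = "nestmax_invalid_move")
  st2 <- nodf_state(staircase3)
  expect_error(apply_move(st2, remove = c(3, 3), add = c(3, 2)),
               class = "nestmax_invalid_move")  # empty source
  expect_error(apply_move(st2, remove = c(1, 1), add = c(2, 2)),
               class = "nestmax_invalid_move")  # occupied target
  expect_error(apply_move(st2, remove = c(3, 1), add = c(3, 3)),
               class = "nestmax_invalid_move")  # would empty row 3
  expect_error(apply_move(st2, remove = c(0, 1), add = c(3, 3)),
               class = "nestmax_invalid_move")  # out of bounds
  expect_equal(st2$current_total, 100)
})

test_that("remove-then-re-add returns the total to its starting value", {
  set.seed(31)
  for (i in 1:10) {
    M <- random_feasible_matrix(random_shape(4, 8, 0.3, 0.6))
    st <- nodf_state(M)
    mv <- propose_move(M)
    st2 <- apply_move(st, mv$remove, mv$add)
    st3 <- apply_move(st2, remove = mv$add, add = mv$remove)
    expect_identical(st3$matrix, st$matrix)
    expect_equal(st3$current_total, st$current_total, tolerance = 1e-9)
  }
})

test_that("cached total tracks from-scratch recomputation over long move chains", {
  set.seed(17)
  for (rep in 1:4) {
    M <- random_feasible_matrix(random_shape(5, 12, 0.2, 0.5))
    st <- nodf_state(M)
    for (k in 1:250) {
      mv <- propose_move(st$matrix)
      st <- apply_move(st, mv$remove, mv$add)
    }
    full <- nodf_total(st$matrix)
    expect_equal(st$current_total, full,
                 tolerance = 1e-9 * max(1, abs(full)))
    expect_feasible(st$matrix)
    expect_equal(sum(st$matrix), sum(as_interaction_matrix(M)))
  }
})
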