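# Independent oracles, deliberately naive: these share no code with the
# package's vectorized/incremental paths.

# NODF by direct double loop over the pair definition
oracle_nodf <- function(M) {
  M <- (M > 0) + 0L
  m <- nrow(M); n <- ncol(M)
  s <- 0
  if (m >= 2) for (i in 1:(m - 1)) for (j in (i + 1):m) {
    di <- sum(M[i, ]); dj <- sum(M[j, ])
    if (di != dj && min(di, dj) > 0)
      s <- s + 100 * sum(M[i, ] * M[j, ]) / min(di, dj)
  }
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    di <- sum(M[, i]); dj <- sum(M[, j])
    if (di != dj && min(di, dj) > 0)
      s <- s + 100 * sum(M[, i] * M[, j]) / min(di, dj)
  }
  s / (choose(m, 2) + choose(n, 2))
}

# number of m x n binary matrices with L ones and no empty row/column,
# by inclusion-exclusion over which rows/columns are forced empty
oracle_feasible_count <- function(m, n, L) {
  total <- 0
  for (i in 0:m) for (j in 0:n)
    total <- total + (-1)^(i + j) * choose(m, i) * choose(n, j) *
      choose((m - i) * (n - j), L)
  total
}

# a random feasible shape with rows, cols in [lo, hi] and the requested
# connectance window (links clamped to feasibility)
random_shape <- function(lo = 5, hi = 15, cmin = 0.15, cmax = 0.4) {
  m <- sample(lo:hi, 1)
  n <- sample(lo:hi, 1)
  L <- max(m, n, round(runif(1, cmin, cmax) * m * n))
  network_shape(m, n, min(L, m * n))
}

expect_feasible <- function(M, shape = NULL) {
  expect_true(all(M %in% c(0L, 1L)))
  expect_true(all(rowSums(M) >= 1))
  expect_true(all(colSums(M) >= 1))
  if (!is.null(shape)) {
    expect_identical(dim(M), c(shape$n_rows, shape$n_cols))
    expect_identical(sum(M), shape$n_links)
  }
}

staircase3 <- rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 0L))
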