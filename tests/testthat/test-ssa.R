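test_that("embedding builds the Hankel trajectory matrix", {
  X <- ssa_embed(1:5, 3)
  expect_identical(X, matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, 3))
  expect_identical(dim(X), c(3L, 3L))  # K = N - L + 1 = 3

  X7 <- ssa_embed(rep(7, 4), 2)
  expect_true(all(X7 == 7))
  expect_equal(qr(X7)$rank, 1L)

  # Hankel property: equal entries along every anti-diagonal
  set.seed(1)
  x <- rnorm(20)
  X <- ssa_embed(x, 7)
  idx <- row(X) + col(X)
  for (s in unique(as.vector(idx)))
    expect_equal(max(X[idx == s]) - min(X[idx == s]), 0)

  expect_error(ssa_embed(1:5, 4), "\\[2, 3\\]")
  expect_error(ssa_embed(1:5, 1), "L")
})

test_that("SVD decomposition has ordered values and reassembles the matrix", {
  # constant series: exactly one nonzero singular value
  dec <- ssa_decompose(ssa_embed(rep(3, 10), 4))
  expect_identical(dec$d, 1L)

  # pure sinusoid: two dominant components carrying > 99.9% of the energy
  s <- sin(2 * pi * (1:200) / 17)
  X <- ssa_embed(s, 50)
  dec <- ssa_decompose(X)
  expect_true(all(diff(dec$values) <= 1e-12))
  expect_gt(sum(dec$values[1:2]^2) / sum(dec$values^2), 0.999)
  # agrees with a direct SVD of the explicitly constructed matrix
  Xexp <- matrix(NA_real_, 50, 151)
  for (i in 1:50) for (j in 1:151) Xexp[i, j] <- s[i + j - 1]
  expect_equal(dec$values[1:2], svd(Xexp)$d[1:2], tolerance = 1e-12)

  # sum of elementary matrices reassembles X
  rebuilt <- dec$u %*% (dec$values * t(dec$v))
  expect_lt(norm(rebuilt - X, "F") / norm(X, "F"), 1e-10)

  expect_error(ssa_decompose(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("grouping splits the matrix conservatively", {
  set.seed(2)
  X <- ssa_embed(rnorm(40), 10)
  dec <- ssa_decompose(X)
  for (I in c(1L, 3L, dec$d)) {
    g <- ssa_group(dec, I)
    expect_lt(norm(g$trend + g$residual - X, "F") / norm(X, "F"), 1e-10)
  }
  expect_lt(norm(ssa_group(dec, dec$d)$residual, "F"), 1e-8 * norm(X, "F"))

  # constant series, I = 1: trend is the whole matrix
  Xc <- ssa_embed(rep(5, 12), 4)
  decc <- ssa_decompose(Xc)
  expect_equal(ssa_group(decc, 1)$trend, Xc, tolerance = 1e-12)

  # sinusoid, I = 2: residual negligible
  Xs <- ssa_embed(sin(2 * pi * (1:200) / 17), 50)
  gs <- ssa_group(ssa_decompose(Xs), 2)
  expect_lt(norm(gs$residual, "F"), 1e-6 * norm(Xs, "F"))

  expect_error(ssa_group(dec, 0), "I")
  expect_error(ssa_group(dec, dec$d + 1L), "I")
})

test_that("diagonal averaging matches hand values, brute force and transpose", {
  expect_equal(diag_average(matrix(c(1, 3, 2, 4), 2)), c(1, 2.5, 4))

  # Hankel round-trip is exact
  set.seed(3)
  for (L in c(2, 5, 9)) {
    x <- rnorm(17)
    expect_identical(diag_average(ssa_embed(x, L)), x)
  }

  # brute-force anti-diagonal oracle on random matrices up to 6 x 8
  for (L in 1:6) for (K in 1:8) {
    M <- matrix(rnorm(L * K), L, K)
    expect_equal(diag_average(M), brute_diag_average(M), tolerance = 1e-12)
  }

  # anti-diagonals are preserved under transposition
  M <- matrix(rnorm(24), 4, 6)
  expect_equal(diag_average(M), diag_average(t(M)), tolerance = 1e-12)

  expect_error(diag_average(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("truncated reconstruction recovers signals of known rank", {
  set.seed(4)
  x <- rnorm(60)
  dec <- ssa_decompose(ssa_embed(x, 20))
  expect_lt(max(abs(ssa_reconstruct(x, 20, dec$d) - x)), 1e-8)

  s <- 3 * sin(2 * pi * (1:200) / 17)
  expect_lt(max(abs(ssa_reconstruct(s, 50, 2) - s)), 1e-6)

  expect_equal(ssa_reconstruct(rep(64, 30), 10, 1), rep(64, 30),
               tolerance = 1e-10)
})

test_that("reconstruction error is non-increasing in the component count", {
  set.seed(5)
  x <- sin(2 * pi * (1:80) / 11) + 0.5 * rnorm(80)
  X <- ssa_embed(x, 25)
  dec <- ssa_decompose(X)
  errs <- vapply(seq_len(dec$d), function(I)
    norm(ssa_group(dec, I)$residual, "F"), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("recurrent forecasting continues constants, ramps and sinusoids", {
  expect_identical(ssa_forecast(rep(72, 40), 10, 1, 0), numeric(0))
  expect_equal(ssa_forecast(rep(72.5, 40), 10, 1, 12), rep(72.5, 12),
               tolerance = 1e-9)
  expect_equal(ssa_forecast(rep(72.5, 500), 30, 1, 5), rep(72.5, 5),
               tolerance = 1e-9)

  ramp <- 4 + 0.25 * (1:100)
  truth <- 4 + 0.25 * (101:110)
  expect_lt(max(abs(ssa_forecast(ramp, 30, 2, 10) - truth) / abs(truth)), 1e-3)

  s <- sin(2 * pi * (1:200) / 17)
  truth <- sin(2 * pi * (201:230) / 17)
  expect_lt(max(abs(ssa_forecast(s, 50, 2, 30) - truth)), 1e-3)

  expect_error(ssa_forecast(1:50, 10, 2, -1), "steps")
})
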