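test_that("shift_cols matches its definition and errors on bad lags", {
  h <- matrix(1:3, 1)
  expect_identical(shift_cols(h, 0, "right"), h)
  expect_equal(shift_cols(h, 1, "right"), matrix(c(0, 1, 2), 1))
  expect_equal(shift_cols(h, 2, "left"), matrix(c(3, 0, 0), 1))
  expect_error(shift_cols(h, 3, "right"), "lag")
  expect_error(shift_cols(h, -1, "right"), "lag")
})

test_that("shift round trips zero out the wrapped-away columns", {
  set.seed(1)
  H <- matrix(runif(40), 4, 10)
  for (l in c(1, 3, 7)) {
    rl <- shift_cols(shift_cols(H, l, "right"), l, "left")
    expect_equal(rl[, 1:(10 - l)], H[, 1:(10 - l)])
    expect_true(all(rl[, (10 - l + 1):10] == 0))
    lr <- shift_cols(shift_cols(H, l, "left"), l, "right")
    expect_equal(lr[, (l + 1):10], H[, (l + 1):10])
    expect_true(all(lr[, 1:l] == 0))
  }
})

test_that("reconstruct handles the degenerate and L = 1 cases", {
  m0 <- factor_model(array(0, c(2, 2, 3)), matrix(1, 2, 6))
  expect_true(all(reconstruct(m0) == 0))
  # L = 1 is plain NMF: outer-product reconstruction
  W <- matrix(c(2, 3), 2, 1)
  H <- matrix(c(1, 0, 2), 1)
  m <- factor_model(W, H)
  expect_equal(reconstruct(m), matrix(c(2, 3, 0, 0, 4, 6), 2, 3))
  set.seed(42)
  W1 <- array(runif(12), c(3, 4, 1))
  H1 <- matrix(runif(20), 4, 5)
  expect_equal(reconstruct(factor_model(W1, H1)),
               matrix(W1, 3, 4) %*% H1, tolerance = 1e-12)
})

test_that("reconstruct and transconv agree with the brute-force oracles", {
  m <- factor_model(array(c(1.0, 0.5), c(1, 1, 2)),
                    matrix(c(0, 1, 0, 0), 1))
  expect_equal(reconstruct(m), matrix(c(0, 1.0, 0.5, 0), 1))
  expect_equal(transconv(array(c(1, 1), c(1, 1, 2)), matrix(1:3, 1)),
               matrix(c(3, 5, 3), 1))
  for (seed in 1:5) {
    set.seed(seed)
    dims <- sample(2:6, 4, replace = TRUE)   # N, K, L, T
    dims[4] <- max(dims[3] + 1, dims[4])
    m <- rand_model(dims[1], dims[2], dims[3], dims[4], seed + 100)
    X <- rand_X(dims[1], dims[4], seed + 200)
    expect_equal(reconstruct(m), oracle_reconstruct(m$W, m$H),
                 tolerance = 1e-10)
    expect_equal(transconv(m$W, X), oracle_transconv(m$W, X),
                 tolerance = 1e-10)
  }
})

test_that("transconv behaves as a matched filter", {
  set.seed(7)
  N <- 5; L <- 4; T <- 60; t0 <- 23
  pattern <- matrix(runif(N * L), N, L)
  X <- matrix(0, N, T)
  X[, t0 + 0:(L - 1)] <- pattern
  W <- array(pattern, c(N, 1, L))
  ov <- transconv(W, X)
  expect_equal(which.max(ov[1, ]), t0)
})

test_that("transconv all-zero data gives all-zero overlap", {
  m <- rand_model(3, 2, 4, 10, 1)
  expect_true(all(transconv(m$W, matrix(0, 3, 10)) == 0))
})

test_that("smooth_rows equals multiplication by the materialized S", {
  A <- matrix(runif(12), 3, 4)
  expect_equal(smooth_rows(A, 1), A)
  expect_equal(smooth_rows(matrix(c(0, 1, 0, 0), 1), 2),
               matrix(c(1, 1, 1, 0), 1))
  set.seed(3)
  B <- matrix(rnorm(60), 3, 20)
  for (L in c(2, 4, 9, 25))
    expect_equal(smooth_rows(B, L), oracle_smooth(B, L), tolerance = 1e-12)
})

test_that("recon_cost is the squared Frobenius distance", {
  expect_equal(recon_cost(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(recon_cost(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 2)
  X <- rand_X(4, 7, 9); Y <- rand_X(4, 7, 10)
  expect_equal(recon_cost(X, Y), sum(mapply(function(a, b) (a - b)^2, X, Y)))
  expect_error(recon_cost(X, Y[, 1:3]), "shape")
})

test_that("xortho_cost matches the materialized-S oracle", {
  # K = 1: empty off-diagonal sum
  m1 <- rand_model(4, 1, 3, 20, 5)
  X <- rand_X(4, 20, 6)
  expect_equal(xortho_cost(m1, X, 1), 0)
  expect_equal(xortho_cost(rand_model(4, 3, 3, 20, 7), X, 0), 0)
  # duplicate factor on data containing its sequence: strictly positive
  set.seed(8)
  W1 <- array(0, c(4, 2, 3))
  pat <- matrix(runif(12), 4, 3)
  W1[, 1, ] <- pat; W1[, 2, ] <- pat
  H1 <- matrix(0, 2, 20); H1[, 5] <- 1; H1[, 12] <- 1
  md <- factor_model(W1, H1)
  Xd <- reconstruct(md)
  expect_gt(xortho_cost(md, Xd, 0.01), 0)
  for (seed in 1:4) {
    m <- rand_model(3, 4, 3, 15, seed)
    Xr <- rand_X(3, 15, seed + 50)
    expect_equal(xortho_cost(m, Xr, 0.7),
                 oracle_xortho(m$W, m$H, Xr, m$L, 0.7), tolerance = 1e-10)
  }
  expect_error(xortho_cost(m1, X, -1), "lam")
})

test_that("xortho_cost is invariant under joint factor permutation", {
  m <- rand_model(4, 5, 3, 25, 11)
  X <- rand_X(4, 25, 12)
  perm <- c(3, 5, 1, 2, 4)
  mp <- factor_model(m$W[, perm, , drop = FALSE], m$H[perm, ])
  expect_equal(xortho_cost(m, X, 0.3), xortho_cost(mp, X, 0.3),
               tolerance = 1e-12)
})

test_that("data_matrix enforces its invariants", {
  expect_error(data_matrix(matrix(c(1, -1), 1)), "negative")
  expect_error(data_matrix(matrix(c(1, NA), 1)), "finite")
  dm <- data_matrix(matrix(1:6, 2), channel_ids = c("a", "b"),
                    bin_seconds = 0.01)
  expect_identical(dm$channel_ids, c("a", "b"))
  expect_error(factor_model(array(-1, c(1, 1, 1)), matrix(1, 1, 2)),
               "nonnegative")
  expect_error(factor_model(array(1, c(2, 2, 2)), matrix(1, 3, 4)),
               "factors")
})
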