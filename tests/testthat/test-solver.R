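# termwise oracles for one multiplicative update, with S materialized
oracle_update_H <- function(m, X, lam = 0, lam_oh = 0, lam_l1h = 0) {
  eps <- max(X) * 1e-10
  K <- m$K; T <- ncol(m$H)
  Xhat <- oracle_reconstruct(m$W, m$H)
  num <- oracle_transconv(m$W, X)
  den <- oracle_transconv(m$W, Xhat)
  oneI <- matrix(1, K, K) - diag(K)
  if (lam > 0) den <- den + lam * oneI %*% (num %*% oracle_S(T, m$L))
  if (lam_oh > 0) den <- den + lam_oh * oneI %*% (m$H %*% oracle_S(T, m$L))
  den <- den + lam_l1h + eps
  m$H * num / den
}

oracle_update_W <- function(m, X, lam = 0, lam_ow = 0, lam_l1w = 0) {
  eps <- max(X) * 1e-10
  K <- m$K; L <- m$L; T <- ncol(m$H)
  Xhat <- oracle_reconstruct(m$W, m$H)
  oneI <- matrix(1, K, K) - diag(K)
  S <- oracle_S(T, L)
  Wflat <- apply(m$W, c(1, 2), sum)
  Wnew <- m$W
  for (l in 0:(L - 1)) {
    Hs <- shift_cols(m$H, l, "right")
    num <- X %*% t(Hs)
    den <- Xhat %*% t(Hs)
    if (lam > 0)
      den <- den + lam * (shift_cols(X, l, "left") %*% S %*% t(m$H)) %*% oneI
    if (lam_ow > 0) den <- den + lam_ow * Wflat %*% oneI
    den <- den + lam_l1w + eps
    Wnew[, , l + 1] <- m$W[, , l + 1] * num / den
  }
  Wnew
}

test_that("update_H and update_W fix points and nonnegativity", {
  # exact reconstruction + zero penalties: multiplicative ratio is 1
  m <- rand_model(3, 2, 3, 30, 1)
  X <- reconstruct(m)
  expect_equal(update_H(m, X)$H, m$H, tolerance = 1e-8)
  expect_equal(update_W(m, X)$W, m$W, tolerance = 1e-8)
  # nonnegativity under arbitrary data and penalties
  Xr <- rand_X(3, 30, 2)
  pen <- penalty_config(lam = 0.1, lam_ortho_h = 0.05, lam_ortho_w = 0.05,
                        lam_l1_w = 0.01, lam_l1_h = 0.01)
  expect_true(all(update_H(m, Xr, pen)$H >= 0))
  expect_true(all(update_W(m, Xr, pen)$W >= 0))
})

test_that("single updates match the materialized-S oracles", {
  for (seed in 1:3) {
    m <- rand_model(2, 2, 2, 6, seed)
    X <- rand_X(2, 6, seed + 10)
    expect_equal(update_H(m, X)$H, oracle_update_H(m, X),
                 tolerance = 1e-10)
    expect_equal(update_W(m, X)$W, oracle_update_W(m, X),
                 tolerance = 1e-10)
    # x-ortho penalty active
    pen <- penalty_config(lam = 0.3)
    expect_equal(update_H(m, X, pen)$H, oracle_update_H(m, X, lam = 0.3),
                 tolerance = 1e-10)
    expect_equal(update_W(m, X, pen)$W, oracle_update_W(m, X, lam = 0.3),
                 tolerance = 1e-10)
    # auxiliary penalties, all at once
    pen2 <- penalty_config(lam_ortho_h = 0.2, lam_ortho_w = 0.15,
                           lam_l1_w = 0.05, lam_l1_h = 0.07)
    expect_equal(update_H(m, X, pen2)$H,
                 oracle_update_H(m, X, lam_oh = 0.2, lam_l1h = 0.07),
                 tolerance = 1e-10)
    expect_equal(update_W(m, X, pen2)$W,
                 oracle_update_W(m, X, lam_ow = 0.15, lam_l1w = 0.05),
                 tolerance = 1e-10)
  }
})

test_that("with L = 1 and no penalties one pass is classical NMF", {
  set.seed(5)
  N <- 4; K <- 3; T <- 12
  m <- rand_model(N, K, 1, T, 6)
  X <- rand_X(N, T, 7)
  eps <- max(X) * 1e-10
  W2 <- matrix(m$W, N, K)
  # H update: H * (W'X) / (W' W H)
  Hnew <- m$H * crossprod(W2, X) / (crossprod(W2, W2 %*% m$H) + eps)
  expect_equal(update_H(m, X)$H, Hnew, tolerance = 1e-12)
  # W update: W * (X H') / (W H H')
  Wnew <- W2 * (X %*% t(m$H)) / (W2 %*% m$H %*% t(m$H) + eps)
  expect_equal(matrix(update_W(m, X)$W, N, K), Wnew, tolerance = 1e-12)
})

test_that("renormalize_model scales without changing the reconstruction", {
  m <- rand_model(3, 3, 4, 25, 8)
  m$H[2, ] <- 0                      # degenerate factor
  before <- reconstruct(m)
  r <- renormalize_model(m)
  norms <- sqrt(rowSums(r$H^2))
  expect_equal(norms[c(1, 3)], c(1, 1))
  expect_true(all(r$H[2, ] == 0))
  expect_equal(r$W[, 2, ], m$W[, 2, ])   # untouched
  expect_equal(reconstruct(r), before, tolerance = 1e-12)
})

test_that("center_factors recenters mass and preserves interior reconstruction", {
  # pattern concentrated at lag 0 with L = 5 moves to lag 2
  W <- array(0, c(2, 1, 5)); W[, 1, 1] <- c(1, 2)
  H <- matrix(0, 1, 40); H[1, c(10, 25)] <- 1
  m <- factor_model(W, H)
  cf <- center_factors(m)
  expect_equal(which(apply(cf$W[, 1, , drop = FALSE], 3, sum) > 0), 3L)
  expect_equal(which(cf$H[1, ] > 0), c(8L, 23L))
  # already centered: unchanged
  expect_equal(center_factors(cf), cf)
  # random model: interior bins identical
  m2 <- rand_model(3, 2, 6, 50, 9)
  c2 <- center_factors(m2)
  L <- 6
  expect_equal(reconstruct(c2)[, (L + 1):(50 - L)],
               reconstruct(m2)[, (L + 1):(50 - L)], tolerance = 1e-10)
})

test_that("cnmf_fit handles degenerate input and is deterministic", {
  cfg <- fit_config(K = 2, L = 3, max_iter = 5, seed = 3)
  z <- cnmf_fit(matrix(0, 3, 20), cfg)
  expect_equal(z$rmse, 0)
  expect_error(cnmf_fit(matrix(-1, 2, 10), cfg), "nonnegative")
  expect_error(cnmf_fit(matrix(1, 2, 3), fit_config(K = 1, L = 5, seed = 1)),
               "L")
  ds <- small_seq_data(T = 1200)
  cfg2 <- fit_config(K = 4, L = 40, penalties = penalty_config(lam = 0.003),
                     max_iter = 15, seed = 42)
  f1 <- cnmf_fit(ds$X, cfg2)
  f2 <- cnmf_fit(ds$X, cfg2)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$model$H, f2$model$H)
  expect_equal(f1$rmse, sqrt(recon_cost(ds$X, reconstruct(f1$model)) /
                               prod(dim(ds$X$X))))
})

test_that("total cost is non-increasing after the first iterations", {
  ds <- small_seq_data(T = 1200)
  ok <- 0L
  for (s in 1:3) {
    f <- cnmf_fit(ds$X, fit_config(K = 4, L = 40,
                                   penalties = penalty_config(lam = 0.003),
                                   max_iter = 30, tol = 0, seed = s))
    tc <- f$cost_history$recon_cost + f$cost_history$penalty_cost
    if (all(diff(tc[5:length(tc)]) <= 1e-6 * tc[5])) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})

test_that("surplus factors are left empty under an adequate penalty", {
  ds <- small_seq_data(T = 1500)     # 3 sequences
  f <- cnmf_fit(ds$X, fit_config(K = 8, L = 40,
                                 penalties = penalty_config(lam = 0.005),
                                 max_iter = 60, seed = 2))
  load <- rowSums(f$model$H)
  # at most the 3 true sequences carry appreciable loadings
  expect_lte(sum(load > 0.05 * max(load)), 4L)
})

test_that("masked fitting reduces to plain fitting and generalizes", {
  ds <- small_seq_data(T = 1200)
  N <- nrow(ds$X$X); T <- ncol(ds$X$X)
  cfg <- fit_config(K = 4, L = 40, max_iter = 20, seed = 11)
  expect_error(cnmf_fit_masked(ds$X, matrix(0, N, T), cfg), "training")
  expect_error(cnmf_fit_masked(ds$X, matrix(2, N, T), cfg), "0 or 1")
  expect_warning(full <- cnmf_fit_masked(ds$X, matrix(1, N, T), cfg),
                 "NA")
  expect_identical(full$fit$model$W, cnmf_fit(ds$X, cfg)$model$W)
  expect_true(is.na(full$test_rmse))
  mask <- make_mask(N, T, holdout_fraction = 0.1, seed = 5)
  res <- cnmf_fit_masked(ds$X, mask, cfg)
  expect_false(is.na(res$test_rmse))
  # correct K on noiseless data: held-out error comparable to training
  expect_lt(res$test_rmse, 2 * max(res$fit$rmse, 1e-6))
})
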