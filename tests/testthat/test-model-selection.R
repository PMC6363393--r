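test_that("skewness matches the adjusted Fisher-Pearson oracle", {
  set.seed(1)
  x <- rexp(200)
  expect_equal(skewness(x), oracle_skewness(x), tolerance = 1e-12)
  expect_true(is.na(skewness(rep(1, 50))))
})

test_that("power_explained has the documented endpoints and invariance", {
  X <- rand_X(4, 10, 1)
  expect_equal(power_explained(X, X), 100)
  expect_equal(power_explained(X, 0 * X), 0)
  # overshoot is penalized: hand example
  expect_equal(power_explained(matrix(c(1, 1), 1), matrix(c(2, 0), 1)), 0)
  expect_error(power_explained(0 * X, X), "zero")
  # invariant to simultaneous row/column permutation
  Xh <- rand_X(4, 10, 2)
  rp <- sample(4); cp <- sample(10)
  expect_equal(power_explained(X, Xh),
               power_explained(X[rp, cp], Xh[rp, cp]), tolerance = 1e-12)
})

test_that("diss endpoints, symmetry and permutation invariance", {
  m <- rand_model(4, 3, 3, 30, 3)
  expect_equal(diss(m, m), 0, tolerance = 1e-12)
  perm <- c(2, 3, 1)
  mp <- factor_model(m$W[, perm, , drop = FALSE], m$H[perm, ])
  expect_equal(diss(m, mp), 0, tolerance = 1e-12)
  # disjoint supports: every cross-correlation 0, diss = 1
  W1 <- array(0, c(4, 2, 2)); W2 <- array(0, c(4, 2, 2))
  W1[1:2, , 1] <- 1; W2[3:4, , 1] <- 1
  H1 <- matrix(0, 2, 20); H1[, 3] <- 1
  f1 <- factor_model(W1, H1); f2 <- factor_model(W2, H1)
  expect_equal(diss(f1, f2), 1)
  m2 <- rand_model(4, 3, 3, 30, 4)
  expect_equal(diss(m, m2), diss(m2, m), tolerance = 1e-12)
  expect_gte(diss(m, m2), 0); expect_lte(diss(m, m2), 1)
  expect_error(diss(m, rand_model(4, 2, 3, 30, 5)), "same K")
})

test_that("similarity_to_truth resolves permutations and flags deficits", {
  m <- rand_model(5, 3, 4, 40, 6)
  expect_equal(similarity_to_truth(m, m), 1, tolerance = 1e-10)
  perm <- c(3, 1, 2)
  mp <- factor_model(m$W[, perm, , drop = FALSE], m$H[perm, ])
  expect_equal(similarity_to_truth(mp, m), 1, tolerance = 1e-10)
  # all-zero fit: nothing matchable
  z <- factor_model(array(0, c(5, 3, 4)), matrix(0, 3, 40))
  s <- similarity_to_truth(z, m)
  expect_equal(as.numeric(s), 0)
  expect_equal(attr(s, "unmatched"), 3L)
})

test_that("factor_significance detects planted factors, rejects noise", {
  ds <- small_seq_data(n_sequences = 2, T = 1500)
  sp <- holdout_split(ds$X)
  truth <- ds$truth
  # significance of the true factors on genuinely held-out data
  res <- factor_significance(truth, sp$test, alpha = 0.05, seed = 1)
  expect_true(all(res$significant))
  expect_equal(res$n_significant, 2L)
  expect_true(all(res$skew > res$threshold))
  # structureless noise: factors should (almost) never pass
  set.seed(9)
  noise <- matrix(rexp(20 * 400), 20, 400)
  mr <- rand_model(20, 3, 10, 400, 10)
  resn <- factor_significance(mr, noise, alpha = 0.05, seed = 2)
  expect_lte(resn$n_significant, 1L)
  # all-zero factor is reported non-significant without testing
  m0 <- truth; m0$W[, 1, ] <- 0
  res0 <- factor_significance(m0, sp$test, seed = 3)
  expect_false(res0$significant[1])
  expect_error(factor_significance(truth, sp$test, alpha = 1.5), "alpha")
  expect_match(factor_significance(truth, sp$test, n_null = 10,
                                   seed = 1)$warning, "n_null")
})

test_that("holdout_split reserves a contiguous tail", {
  X <- matrix(seq_len(40), 4, 10)
  sp <- holdout_split(X, 0.3)
  expect_equal(ncol(sp$train), 7)
  expect_equal(ncol(sp$test), 3)
  expect_equal(cbind(sp$train, sp$test), X)
})

test_that("lambda_sweep finds a reproducible crossover", {
  ds <- small_seq_data(T = 1200)
  cfg <- fit_config(K = 5, L = 40, max_iter = 25, seed = 7)
  grid <- 10^seq(-4, -1, length.out = 6)
  sw1 <- lambda_sweep(ds$X, cfg, lambdas = grid)
  expect_true(all(sw1$recon_curve >= 0 & sw1$recon_curve <= 1))
  expect_true(all(sw1$xortho_curve >= 0 & sw1$xortho_curve <= 1))
  expect_gte(sw1$lambda0, min(grid)); expect_lte(sw1$lambda0, max(grid))
  expect_equal(sw1$recommended, 3 * sw1$lambda0)
  sw2 <- lambda_sweep(ds$X, cfg, lambdas = grid)
  expect_identical(sw1$lambda0, sw2$lambda0)    # bitwise reproducible
  # a grid confined below the crossover cannot bracket it
  expect_error(lambda_sweep(ds$X, cfg,
                            lambdas = 10^seq(-8, -7, length.out = 3)),
               "widen")
})

test_that("select_k recovers the true factor count on easy fixtures", {
  ds1 <- small_seq_data(n_sequences = 1, T = 1200)
  cfg <- fit_config(K = 1, L = 40, max_iter = 30, seed = 5)
  rep1 <- select_k(ds1$X, k_values = 1:3, n_fits = 3, config = cfg)
  expect_equal(rep1$k_selected, 1L)
  expect_true(all(unlist(rep1$diss_samples) >= 0 &
                    unlist(rep1$diss_samples) <= 1))
})

test_that("sequenciness is near zero for purely synchronous data", {
  ds <- make_mixture(p_sequence = 0, T = 1500, seed = 3)
  s <- sequenciness(ds$X, K = 2, L = 12, n_shuffle = 7, seed = 4)
  expect_lt(abs(s$score), 0.15)
  expect_false(s$significant)
  ds1 <- make_mixture(p_sequence = 1, T = 1500, seed = 3)
  s1 <- sequenciness(ds1$X, K = 2, L = 12, n_shuffle = 7, seed = 4)
  expect_gt(s1$score, 0.7)
  expect_true(s1$significant)
})
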