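#' Adjusted Fisher--Pearson sample skewness
#'
#' Bias-corrected skewness `G1 = g1 * sqrt(n(n-1))/(n-2)` with
#' `g1 = m3 / m2^(3/2)`.  Returns `NA` for constant input.
#'
#' @param x numeric vector.
#' @return Scalar skewness.
#' @export
skewness <- function(x) cpp_skewness(as.numeric(x))

#' Held-out significance test for each factor
#'
#' A factor that captures a real sequence overlaps held-out data
#' strongly at the times the sequence occurs and weakly elsewhere, so
#' the distribution over timebins of its overlap trace
#' (row k of \eqn{W \circledast^\top X_{test}}) is strongly
#' right-skewed.  The null distribution of skewness is estimated from
#' factors whose temporal structure has been destroyed: each channel's
#' lag profile within the exemplar is independently circularly shifted
#' by a uniform integer in `[0, L)`.  Factor k is significant when its
#' skewness exceeds the Bonferroni-corrected `(1 - alpha/K)` quantile
#' of its null skews.
#'
#' The held-out data must be disjoint in time from the data the model
#' was fit to (see [holdout_split()]); this is the caller's
#' responsibility.
#'
#' @param model a [factor_model()].
#' @param X_test held-out data matrix (N x T_test).
#' @param alpha family significance level in (0, 1).
#' @param n_null number of null factors per real factor; the default
#'   `ceiling(5 * K / alpha)` makes the corrected quantile estimable.
#' @param empty_tol factors whose reconstruction power
#'   ([factor_powers()]) is below `empty_tol` times the largest
#'   factor's power are treated as empty: reported non-significant
#'   without testing.  Suppressed factors retain a vanishing imprint of
#'   the data (and skewness is scale invariant), so a relative
#'   amplitude floor is needed; suppression leaves a gap of many orders
#'   of magnitude, so the default is not delicate.
#' @param seed integer seed for the null shifts.
#' @return An object of class `significance_result`: `skew` (K),
#'   `null_skews` (K x n_null), `threshold` (K), `significant` (K
#'   logical), `alpha`, `n_significant`, and `warning` (character,
#'   present when `n_null` is too small for the requested quantile).
#' @export
factor_significance <- function(model, X_test, alpha = 0.05,
                                n_null = NULL, empty_tol = 1e-6,
                                seed = 1L) {
  stopifnot(inherits(model, "factor_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("factor_significance: alpha must lie in (0, 1)")
  X_test <- dm_mat(X_test)
  K <- model$K; L <- model$L; N <- dim(model$W)[1L]
  if (is.null(n_null)) n_null <- as.integer(ceiling(5 * K / alpha))
  warn <- character(0)
  if (n_null < K / alpha)
    warn <- sprintf(
      "n_null = %d is below K/alpha = %.0f; the (1 - alpha/K) quantile is poorly estimated",
      n_null, K / alpha)
  overlap <- cpp_transconv(model$W, X_test)
  skew <- apply(overlap, 1L, function(r) cpp_skewness(r))
  powers <- factor_powers(model)
  empty <- powers <= empty_tol * max(powers)
  null_skews <- matrix(NA_real_, K, n_null)
  threshold <- rep(NA_real_, K)
  significant <- rep(FALSE, K)
  set.seed(seed)
  for (k in seq_len(K)) {
    if (empty[k]) next               # empty factor: never significant
    Wk <- matrix(model$W[, k, ], N, L)
    shifts <- matrix(sample.int(L, N * n_null, replace = TRUE) - 1L,
                     N, n_null)
    null_skews[k, ] <- cpp_null_skews(Wk, X_test, shifts)
    threshold[k] <- quantile(null_skews[k, ], 1 - alpha / K,
                             na.rm = TRUE, names = FALSE)
    significant[k] <- is.finite(skew[k]) && skew[k] > threshold[k]
  }
  structure(list(skew = skew, null_skews = null_skews,
                 threshold = threshold, significant = significant,
                 empty = empty, powers = powers,
                 alpha = alpha, n_null = n_null,
                 n_significant = sum(significant),
                 warning = warn),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %d of %d factors significant (alpha = %g)\n",
              x$n_significant, length(x$significant), x$alpha))
  invisible(x)
}

#' Split a data matrix into a training block and a held-out tail
#'
#' Reserves the final `test_fraction` of timebins as held-out data for
#' [factor_significance()].  A contiguous split avoids leaking
#' instances of a sequence across the train/test boundary.
#'
#' @param X N x T matrix or [data_matrix()].
#' @param test_fraction fraction of timebins in the test tail.
#' @return List with matrices `train` and `test`.
#' @export
holdout_split <- function(X, test_fraction = 0.25) {
  Xm <- dm_mat(X)
  T <- ncol(Xm)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- max(1L, round(test_fraction * T))
  list(train = Xm[, seq_len(T - n_test), drop = FALSE],
       test = Xm[, (T - n_test + 1L):T, drop = FALSE])
}

#' Percent of total power explained by a reconstruction
#'
#' \eqn{100 \cdot \sum(2 X \tilde{X} - \tilde{X}^2) / \sum X^2}; equals
#' 100 when the reconstruction is exact, 0 when it is identically zero,
#' and penalizes overshoot (it can be negative).
#'
#' @param X data matrix.
#' @param Xhat reconstruction of the same shape.
#' @return Scalar percentage in \eqn{(-\infty, 100]}.
#' @export
power_explained <- function(X, Xhat) {
  X <- dm_mat(X); Xhat <- dm_mat(Xhat)
  if (!identical(dim(X), dim(Xhat)))
    stop("power_explained: X and Xhat must have the same shape")
  denom <- sum(X^2)
  if (denom == 0) stop("power_explained: X is identically zero")
  100 * sum(2 * X * Xhat - Xhat^2) / denom
}

#' Sequenciness of a dataset
#'
#' Quantifies how much of the structure captured by unpenalized
#' convolutional NMF is genuinely sequential rather than synchronous.
#' Column-shuffling a data matrix destroys sequences but leaves
#' synchronous (rank-one) patterns learnable, whereas shuffling each
#' row by its own random permutation destroys all temporal structure.
#' The score is
#' `(P_actual - median P_colshuffle) / (P_actual - median P_rowshuffle)`
#' where P is the percent power explained by a fresh fit to each
#' matrix: approximately 0 for purely synchronous data and close to 1
#' for pure sequences.  Significance is assessed per dataset against
#' the `(1 - alpha)` quantile of the column-shuffled powers.
#'
#' @param X N x T matrix or [data_matrix()].
#' @param K,L factorization size for the unpenalized fits.
#' @param n_shuffle number of shuffles of each kind.
#' @param fit_config optional [fit_config()] template; its `K`, `L`
#'   and penalties are overridden (penalties are forced to zero).
#' @param alpha significance level for the column-shuffle test.
#' @param seed integer seed.
#' @return List with `score` (NA with a `diagnostic` element when the
#'   denominator is not positive), `significant`, `p_actual`,
#'   `p_colshuffle`, `p_rowshuffle`, `threshold`.
#' @export
sequenciness <- function(X, K = 2L, L = 12L, n_shuffle = 15L,
                         fit_config = NULL, alpha = 0.05, seed = 1L) {
  Xm <- dm_mat(X)
  T <- ncol(Xm); N <- nrow(Xm)
  base_cfg <- function(s) {
    if (is.null(fit_config))
      convnmf::fit_config(K = K, L = L, max_iter = 50L, seed = s)
    else {
      cfg <- fit_config
      cfg$K <- as.integer(K); cfg$L <- as.integer(L)
      cfg$penalties <- penalty_config()
      cfg$seed <- as.integer(s)
      cfg
    }
  }
  fit_power <- function(M, s) {
    f <- cnmf_fit(M, base_cfg(s))
    power_explained(M, reconstruct(f$model))
  }
  p_actual <- fit_power(Xm, seed)
  set.seed(seed)
  p_col <- numeric(n_shuffle)
  p_row <- numeric(n_shuffle)
  for (i in seq_len(n_shuffle)) {
    col_perm <- sample.int(T)
    Xc <- Xm[, col_perm, drop = FALSE]
    Xr <- t(apply(Xm, 1L, function(r) r[sample.int(T)]))
    p_col[i] <- fit_power(Xc, seed + i)
    p_row[i] <- fit_power(Xr, seed + n_shuffle + i)
  }
  num <- p_actual - median(p_col)
  den <- p_actual - median(p_row)
  threshold <- quantile(p_col, 1 - alpha, names = FALSE)
  out <- list(score = if (den > 0) num / den else NA_real_,
              significant = p_actual > threshold,
              p_actual = p_actual, p_colshuffle = p_col,
              p_rowshuffle = p_row, threshold = threshold)
  if (den <= 0)
    out$diagnostic <- "power explained is indistinguishable from fully shuffled data"
  out
}

#' Sweep the cross-orthogonality weight and locate the crossover
#'
#' Fits the model over a grid of penalty weights; as lambda grows the
#' reconstruction cost rises and the x-ortho cost falls.  Both mean
#' cost curves are min--max normalized to `[0, 1]` and the crossover
#' `lambda0` located by log-linear interpolation between the bracketing
#' grid points.  Weights between `2 * lambda0` and `5 * lambda0`
#' typically recover the correct number of sequences; the `recommended`
#' value is `3 * lambda0`.
#'
#' @param X N x T matrix or [data_matrix()].
#' @param config a [fit_config()]; its `penalties$lam` is overridden by
#'   each grid value.
#' @param lambdas increasing positive grid; default 20 log-spaced
#'   points spanning `1e-4` to `1e-1`.
#' @param n_fits seeded fits per grid point (means are taken across
#'   fits).
#' @return An object of class `lambda_sweep` with `lambdas`,
#'   `recon_curve`, `xortho_curve` (normalized), `recon_cost`,
#'   `xortho_cost` (raw means), `lambda0`, `recommended`.
#' @export
lambda_sweep <- function(X, config, lambdas = NULL, n_fits = 1L) {
  Xm <- dm_mat(X)
  if (is.null(lambdas))
    lambdas <- 10^seq(-4, -1, length.out = 20L)
  stopifnot(length(lambdas) >= 2L, all(diff(lambdas) > 0),
            all(lambdas > 0), n_fits >= 1L)
  recon_mean <- numeric(length(lambdas))
  xortho_mean <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    rc <- xc <- numeric(n_fits)
    for (j in seq_len(n_fits)) {
      cfg <- config
      cfg$penalties$lam <- lambdas[i]
      cfg$seed <- as.integer(config$seed + (j - 1L))
      f <- cnmf_fit(Xm, cfg)
      Xhat <- reconstruct(f$model)
      rc[j] <- recon_cost(Xm, Xhat)
      xc[j] <- xortho_cost(f$model, Xm, 1)   # raw cost term, no lambda
    }
    recon_mean[i] <- mean(rc)
    xortho_mean[i] <- mean(xc)
  }
  # a grid on which neither cost moves appreciably cannot bracket the
  # crossover; normalizing near-constant curves would amplify noise
  if (diff(range(recon_mean)) <= 1e-3 * mean(recon_mean) ||
      diff(range(xortho_mean)) <= 1e-3 * mean(abs(xortho_mean)))
    stop("lambda_sweep: costs barely vary across the grid; ",
         "widen the lambda grid")
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] == r[1]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  rn <- norm01(recon_mean)
  xn <- norm01(xortho_mean)
  d <- rn - xn                 # negative before crossover, positive after
  idx <- which(d[-length(d)] < 0 & d[-1] >= 0)
  if (!length(idx))
    stop("lambda_sweep: cost curves do not cross within the grid; ",
         "widen the lambda grid")
  i <- idx[1L]
  # log-linear interpolation between the bracketing grid points
  la <- log(lambdas[i]); lb <- log(lambdas[i + 1L])
  frac <- if (d[i + 1L] == d[i]) 0 else -d[i] / (d[i + 1L] - d[i])
  lambda0 <- exp(la + frac * (lb - la))
  structure(list(lambdas = lambdas,
                 recon_curve = rn, xortho_curve = xn,
                 recon_cost = recon_mean, xortho_cost = xortho_mean,
                 lambda0 = lambda0, recommended = 3 * lambda0),
            class = "lambda_sweep")
}

#' @export
print.lambda_sweep <- function(x, ...) {
  cat(sprintf("<lambda_sweep> %d points in [%g, %g]; lambda0 = %.4g, recommended = %.4g\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              x$lambda0, x$recommended))
  invisible(x)
}

#' Per-factor reconstruction power
#'
#' The squared Frobenius norm of each factor's own reconstruction
#' \eqn{w_k \circledast h_k}.  Penalized fits leave surplus factors
#' with power many orders of magnitude below the live ones, so this is
#' the natural statistic for deciding which factors are empty.
#'
#' @param model a [factor_model()].
#' @return Numeric vector of K nonnegative powers.
#' @export
factor_powers <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  N <- dim(model$W)[1L]
  vapply(seq_len(model$K), function(k) {
    Wk <- array(model$W[, k, ], c(N, 1L, model$L))
    sum(cpp_reconstruct(Wk, matrix(model$H[k, ], 1L))^2)
  }, numeric(1))
}

# per-factor reconstructions as an N x T x K array
factor_recons <- function(model) {
  N <- dim(model$W)[1L]; T <- ncol(model$H)
  out <- array(0, c(N, T, model$K))
  for (k in seq_len(model$K)) {
    Wk <- array(model$W[, k, ], c(N, 1L, model$L))
    out[, , k] <- cpp_reconstruct(Wk, matrix(model$H[k, ], 1L))
  }
  out
}

#' Dissimilarity between two factorizations
#'
#' Stability metric in `[0, 1]`: the per-factor reconstructions of both
#' models are cross-correlated (normalized inner products of
#' \eqn{\tilde{X}_k}); `diss` is low when factors match one-to-one
#' (0 for identical models up to factor permutation) and 1 when no
#' factor of one model resembles any factor of the other.  Working
#' with reconstructions rather than W or H removes the temporal
#' degeneracy of convolutional factors.  Factors whose reconstruction
#' is identically zero contribute zero correlation (maximally
#' dissimilar).
#'
#' @param f1,f2 [factor_model()]s with equal K over the same data
#'   dimensions.
#' @return Scalar dissimilarity in `[0, 1]`.
#' @export
diss <- function(f1, f2) {
  stopifnot(inherits(f1, "factor_model"), inherits(f2, "factor_model"))
  if (f1$K != f2$K)
    stop("diss: factorizations must have the same K")
  K <- f1$K
  R1 <- factor_recons(f1)
  R2 <- factor_recons(f2)
  M1 <- matrix(R1, ncol = K)    # columns: vectorized reconstructions
  M2 <- matrix(R2, ncol = K)
  n1 <- sqrt(colSums(M1^2))
  n2 <- sqrt(colSums(M2^2))
  C <- crossprod(M1, M2)
  scale <- outer(n1, n2)
  C <- ifelse(scale > 0, C / scale, 0)
  (2 * K - sum(apply(C, 1L, max)) - sum(apply(C, 2L, max))) / (2 * K)
}

#' Select the number of factors by stability
#'
#' For each candidate K, runs `n_fits` unpenalized fits from distinct
#' seeds, computes [diss()] for every unique pair, and selects the K
#' minimizing the median dissimilarity: at the true number of
#' sequences, independent runs agree (low diss), whereas surplus or
#' insufficient factors split or merge sequences inconsistently.
#'
#' @param X N x T matrix or [data_matrix()].
#' @param k_values integer candidates for K.
#' @param n_fits fits per K (>= 2; pairs are needed).
#' @param config a [fit_config()] template; `K` is overridden, the
#'   penalties are forced to zero unless `penalized = TRUE`.
#' @param penalized keep the template's penalties instead of fitting
#'   unpenalized.
#' @return An object of class `diss_report` with `k_values`,
#'   `diss_samples` (list of pairwise diss values per K),
#'   `median_diss`, `k_selected`.
#' @export
select_k <- function(X, k_values = 1:8, n_fits = 5L, config,
                     penalized = FALSE) {
  stopifnot(n_fits >= 2L)
  Xm <- dm_mat(X)
  diss_samples <- vector("list", length(k_values))
  median_diss <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    models <- vector("list", n_fits)
    for (j in seq_len(n_fits)) {
      cfg <- config
      cfg$K <- as.integer(k_values[i])
      if (!penalized) cfg$penalties <- penalty_config()
      cfg$seed <- as.integer(config$seed + (j - 1L) * 1000L + k_values[i])
      models[[j]] <- cnmf_fit(Xm, cfg)$model
    }
    pairs <- utils::combn(n_fits, 2L)
    dvals <- apply(pairs, 2L, function(p)
      diss(models[[p[1L]]], models[[p[2L]]]))
    diss_samples[[i]] <- dvals
    median_diss[i] <- median(dvals)
  }
  structure(list(k_values = as.integer(k_values),
                 diss_samples = diss_samples,
                 median_diss = median_diss,
                 k_selected = as.integer(k_values[which.min(median_diss)])),
            class = "diss_report")
}

#' @export
print.diss_report <- function(x, ...) {
  cat("<diss_report> median diss by K:\n")
  print(stats::setNames(round(x$median_diss, 4), x$k_values))
  cat("selected K =", x$k_selected, "\n")
  invisible(x)
}

#' Greedy similarity of a factorization to ground truth
#'
#' Matches each ground-truth factor, in order, to the unused fitted
#' factor whose per-factor reconstruction has the highest Pearson
#' correlation with the truth factor's reconstruction, and returns the
#' mean matched correlation.  Invariant to factor permutation.  When
#' fewer usable fitted factors than truth factors remain, the leftover
#' truth factors score 0 and the result carries the attribute
#' `unmatched`.
#'
#' @param fit fitted [factor_model()].
#' @param truth ground-truth [factor_model()] over the same data
#'   dimensions.
#' @return Scalar in `[0, 1]` (correlations are clamped at 0).
#' @export
similarity_to_truth <- function(fit, truth) {
  stopifnot(inherits(fit, "factor_model"), inherits(truth, "factor_model"))
  Rt <- factor_recons(truth)
  Rf <- factor_recons(fit)
  Kt <- truth$K; Kf <- fit$K
  Mt <- matrix(Rt, ncol = Kt)
  Mf <- matrix(Rf, ncol = Kf)
  usable <- which(apply(Mf, 2L, function(v) sd(v) > 0))
  used <- integer(0)
  cors <- numeric(Kt)
  unmatched <- 0L
  for (k in seq_len(Kt)) {
    avail <- setdiff(usable, used)
    if (!length(avail) || sd(Mt[, k]) == 0) { unmatched <- unmatched + 1L; next }
    cc <- vapply(avail, function(j) cor(Mt[, k], Mf[, j]), numeric(1))
    best <- which.max(cc)
    cors[k] <- max(0, cc[best])
    used <- c(used, avail[best])
  }
  out <- mean(cors)
  if (unmatched > 0L) attr(out, "unmatched") <- unmatched
  out
}
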