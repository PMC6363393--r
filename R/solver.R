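#' Penalty configuration for the multiplicative updates
#'
#' All weights default to zero (plain convolutional NMF).  `lam` is the
#' cross-orthogonality weight; `lam_ortho_h` penalizes smoothed
#' correlations between loadings rows (favors events-based
#' factorizations of shared channels), `lam_ortho_w` penalizes
#' correlations between lag-summed exemplars (favors parts-based
#' factorizations), and `lam_l1_w` / `lam_l1_h` add L1 sparsity.
#' Several penalties may be active at once; their derivative terms add
#' in the shared update denominator.
#'
#' @param lam cross-orthogonality weight, >= 0.
#' @param lam_ortho_h smoothed orthogonality weight on H, >= 0.
#' @param lam_ortho_w orthogonality weight on lag-summed W, >= 0.
#' @param lam_l1_w,lam_l1_h L1 sparsity weights, >= 0.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lam = 0, lam_ortho_h = 0, lam_ortho_w = 0,
                           lam_l1_w = 0, lam_l1_h = 0) {
  w <- c(lam = lam, lam_ortho_h = lam_ortho_h, lam_ortho_w = lam_ortho_w,
         lam_l1_w = lam_l1_w, lam_l1_h = lam_l1_h)
  if (any(!is.finite(w)) || any(w < 0))
    stop("penalty_config: all weights must be finite and >= 0")
  structure(as.list(w), class = "penalty_config")
}

#' Fitting configuration
#'
#' @param K number of factors, >= 1.
#' @param L number of lags per exemplar, >= 1 and < T of the data.
#' @param penalties a [penalty_config()].
#' @param max_iter maximum number of multiplicative-update iterations.
#' @param tol convergence tolerance: stop when the relative change of
#'   the total cost, averaged over the last 5 iterations, drops below
#'   `tol`.
#' @param seed integer seed; fits with the same seed are bit-identical.
#' @param shift_center if `TRUE`, factors are recentered in time every
#'   iteration so each exemplar's center of mass sits at lag
#'   `floor(L/2)`.
#' @param final_unregularized_step if `TRUE`, run one last H then W
#'   update with all penalty weights zero, restoring loading peaks that
#'   the penalty slightly suppresses near neighboring sequences.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(K, L, penalties = penalty_config(),
                       max_iter = 100L, tol = 1e-6, seed = 1L,
                       shift_center = TRUE,
                       final_unregularized_step = TRUE) {
  stopifnot(K >= 1, K == round(K), L >= 1, L == round(L),
            max_iter >= 1, tol >= 0,
            inherits(penalties, "penalty_config"))
  structure(list(K = as.integer(K), L = as.integer(L),
                 penalties = penalties,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed),
                 shift_center = isTRUE(shift_center),
                 final_unregularized_step = isTRUE(final_unregularized_step)),
            class = "fit_config")
}

# internal: denominator stabilizer; avoids 0/0 without moving fixed points
fit_eps <- function(X) {
  m <- max(X)
  if (m > 0) m * 1e-10 else 1e-12
}

#' One multiplicative update of the loadings H
#'
#' H is multiplied elementwise by numerator / denominator with
#' numerator \eqn{W \circledast^\top X} and denominator
#' \eqn{W \circledast^\top \tilde{X}} plus the active penalty
#' derivatives and a small stabilizer.  W is untouched; nonnegativity
#' is preserved by construction.
#'
#' @param model a [factor_model()].
#' @param X data matrix (or [data_matrix()]).
#' @param penalties a [penalty_config()].
#' @return The updated `factor_model`.
#' @export
update_H <- function(model, X, penalties = penalty_config()) {
  X <- dm_mat(X)
  Xhat <- cpp_reconstruct(model$W, model$H)
  model$H <- update_H_core(model$W, model$H, X, Xhat, penalties,
                           fit_eps(X))$H
  model
}

# Z is the surrogate data (equal to X except at masked entries);
# Xhat must be the reconstruction of the current (W, H).  Also returns
# the raw x-ortho cost of the incoming (W, H), since its expensive
# ingredient (the smoothed overlap) is computed here anyway.
update_H_core <- function(W, H, Z, Xhat, pen, eps) {
  L <- dim(W)[3L]
  K <- nrow(H)
  num <- cpp_transconv(W, Z)
  den <- cpp_transconv(W, Xhat)
  xortho_raw <- 0
  if (K > 1L && pen$lam > 0) {
    sm <- cpp_smooth_rows(num, L)
    C <- sm %*% t(H)
    xortho_raw <- sum(abs(C)) - sum(abs(diag(C)))
    den <- den + pen$lam * colsum_others(sm)
  }
  if (pen$lam_ortho_h > 0 && K > 1L)
    den <- den + pen$lam_ortho_h * colsum_others(cpp_smooth_rows(H, L))
  if (pen$lam_l1_h > 0)
    den <- den + pen$lam_l1_h
  list(H = H * num / (den + eps), xortho_raw = xortho_raw)
}

# (1 - I) %*% A for K x T matrices: row k becomes the sum of all other rows
colsum_others <- function(A) {
  if (nrow(A) == 1L) return(matrix(0, 1L, ncol(A)))
  sweep(-A, 2L, colSums(A), `+`)
}

#' One multiplicative update of the exemplars W
#'
#' For each lag, the N x K slice of W is multiplied elementwise by
#' \eqn{X (H_{\ell\to})^\top} over \eqn{\tilde{X} (H_{\ell\to})^\top}
#' plus penalty derivatives and a stabilizer.  H is untouched.
#'
#' @inheritParams update_H
#' @return The updated `factor_model`.
#' @export
update_W <- function(model, X, penalties = penalty_config()) {
  X <- dm_mat(X)
  Xhat <- cpp_reconstruct(model$W, model$H)
  model$W <- update_W_core(model$W, model$H, X, Xhat, penalties,
                           fit_eps(X))
  model
}

update_W_core <- function(W, H, Z, Xhat, pen, eps, SH = NULL) {
  L <- dim(W)[3L]
  K <- dim(W)[2L]
  N <- dim(W)[1L]
  if (is.null(SH)) SH <- cpp_lag_stack(H, L)
  nd <- cpp_lag_outer2(Z, Xhat, SH, K, L)
  num <- nd$num
  den <- nd$den
  if (pen$lam > 0 && K > 1L) {
    SHt <- t(cpp_smooth_rows(H, L))         # T x K
    xsh <- cpp_lag_left_prod(Z, SHt, L)     # slices: (Z shifted left l) S H'
    for (l in seq_len(L))
      den[, , l] <- matrix(den[, , l], N, K) +
        pen$lam * rowsum_others(matrix(xsh[, , l], N, K))
  }
  if (pen$lam_ortho_w > 0 && K > 1L) {
    Wflat <- matrix(apply(W, c(1L, 2L), sum), N, K)
    term <- pen$lam_ortho_w * rowsum_others(Wflat)
    for (l in seq_len(L))
      den[, , l] <- matrix(den[, , l], N, K) + term
  }
  if (pen$lam_l1_w > 0)
    den <- den + pen$lam_l1_w
  W * num / (den + eps)
}

# A %*% (1 - I) for N x K matrices: column k becomes the sum of the others
rowsum_others <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) == 1L) return(matrix(0, nrow(A), 1L))
  sweep(-A, 1L, rowSums(A), `+`)
}

#' Rescale factors so rows of H have unit norm
#'
#' Each row k of H is divided by its Euclidean norm and the matching
#' exemplar slice multiplied by it, leaving the reconstruction exactly
#' unchanged.  All-zero loadings rows are left untouched.
#'
#' @param model a [factor_model()].
#' @return The rescaled `factor_model`.
#' @export
renormalize_model <- function(model) {
  norms <- sqrt(rowSums(model$H^2))
  for (k in seq_len(model$K)) {
    if (norms[k] > 0) {
      model$H[k, ] <- model$H[k, ] / norms[k]
      model$W[, k, ] <- model$W[, k, ] * norms[k]
    }
  }
  model
}

#' Center each exemplar's mass in the lag window
#'
#' Shifts every factor's exemplar along the lag axis (zero padded) so
#' its lag-wise center of mass lands at lag floor(L/2), and shifts the
#' loadings row oppositely.  The reconstruction is unchanged except
#' within L bins of the time edges, where shifted loadings fall off the
#' recording.  Prevents patterns drifting against the edge of the lag
#' window during fitting.
#'
#' @param model a [factor_model()].
#' @return The recentered `factor_model`.
#' @export
center_factors <- function(model) {
  L <- model$L
  T <- ncol(model$H)
  if (L == 1L) return(model)
  target <- floor(L / 2)          # 0-based target lag
  N <- dim(model$W)[1L]
  for (k in seq_len(model$K)) {
    Wk <- matrix(model$W[, k, ], N, L)
    mass <- colSums(Wk)
    tot <- sum(mass)
    if (tot <= 0) next
    com <- sum((seq_len(L) - 1L) * mass) / tot
    s <- as.integer(round(target - com))   # >0: delay W, advance H
    if (s == 0L || abs(s) >= L || abs(s) >= T) next
    shifted <- matrix(0, nrow(Wk), L)
    if (s > 0L) shifted[, (s + 1L):L] <- Wk[, 1L:(L - s)]
    else        shifted[, 1L:(L + s)] <- Wk[, (1L - s):L]
    model$W[, k, ] <- shifted
    h <- matrix(model$H[k, ], 1L)
    model$H[k, ] <- if (s > 0L) shift_cols(h, s, "left")
                    else        shift_cols(h, -s, "right")
  }
  model
}

#' Fit a penalized convolutional NMF model
#'
#' Initializes W and H uniformly at random (scaled by
#' `mean(X)/sqrt(K*L)`) under the configured seed, then iterates
#' multiplicative updates: H update, recentering, renormalization, W
#' update, until `max_iter` or until the relative cost change averaged
#' over the last five iterations drops below `tol`.  If
#' `final_unregularized_step` is set, one last H-then-W update with all
#' penalty weights zero is run at the end.  Repeated calls with the
#' same seed are bit-identical.
#'
#' @param X nonnegative N x T matrix or [data_matrix()].
#' @param config a [fit_config()].
#' @return An object of class `cnmf_fit` with elements `model`
#'   (the fitted [factor_model()]), `cost_history` (data frame with
#'   columns `iteration`, `recon_cost`, `penalty_cost`), `rmse`
#'   (`sqrt(recon_cost / (N*T))` of the final model), `converged`,
#'   `seed`, and `config`.
#' @examples
#' ds <- make_sequences(sequence_spec(n_sequences = 1, T = 500,
#'                                    target_instances_per_seq = 5, seed = 1))
#' fit <- cnmf_fit(ds$X, fit_config(K = 2, L = 40, max_iter = 30, seed = 1))
#' fit$rmse
#' @export
cnmf_fit <- function(X, config) {
  fit_engine(X, config, mask = NULL)$fit
}

#' Fit with randomly held-out (masked) entries
#'
#' Entries of `X` where `mask` is zero are treated as missing: a
#' surrogate matrix Z, equal to X at observed entries and to the
#' current reconstruction at held-out entries, replaces X in every
#' update numerator and penalty term.  The returned `test_rmse` is the
#' root-mean-squared reconstruction error restricted to held-out
#' entries, the cross-validation statistic for choosing K or lambda.
#'
#' @param X nonnegative N x T matrix or [data_matrix()].
#' @param mask binary N x T matrix; 0 marks held-out test entries.
#'   Typically 5 to 10 percent of entries are held out.
#' @param config a [fit_config()].
#' @return A list with elements `fit` (a `cnmf_fit`) and `test_rmse`.
#'   With an all-ones mask the fit is identical to [cnmf_fit()] and
#'   `test_rmse` is `NA` (with a warning): there are no test entries.
#' @export
cnmf_fit_masked <- function(X, mask, config) {
  Xm <- dm_mat(X)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(Xm)))
    stop("cnmf_fit_masked: mask must have the same shape as X")
  if (!all(mask %in% c(0, 1)))
    stop("cnmf_fit_masked: mask entries must be 0 or 1")
  if (all(mask == 0))
    stop("cnmf_fit_masked: mask holds out every entry; no training data")
  all_ones <- all(mask == 1)
  res <- fit_engine(X, config, mask = if (all_ones) NULL else mask)
  if (all_ones) {
    warning("cnmf_fit_masked: mask holds out no entries; test_rmse is NA")
    test_rmse <- NA_real_
  } else {
    Xhat <- cpp_reconstruct(res$fit$model$W, res$fit$model$H)
    held <- mask == 0
    test_rmse <- sqrt(mean((Xm[held] - Xhat[held])^2))
  }
  list(fit = res$fit, test_rmse = test_rmse)
}

#' Build a random holdout mask
#'
#' @param N,T matrix dimensions.
#' @param holdout_fraction fraction of entries held out, in (0, 1).
#' @param seed integer seed.
#' @return Binary N x T matrix with 0 marking held-out entries.
#' @export
make_mask <- function(N, T, holdout_fraction = 0.1, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  set.seed(seed)
  mask <- matrix(1, N, T)
  n_hold <- round(holdout_fraction * N * T)
  mask[sample.int(N * T, n_hold)] <- 0
  mask
}

# shared fitting engine; mask = NULL means no held-out entries
fit_engine <- function(X, config, mask = NULL) {
  stopifnot(inherits(config, "fit_config"))
  Xm <- dm_mat(X)
  if (any(Xm < 0)) stop("cnmf_fit: X must be nonnegative")
  N <- nrow(Xm); T <- ncol(Xm)
  K <- config$K; L <- config$L
  if (L >= T) stop(sprintf("cnmf_fit: L = %d must be < T = %d", L, T))
  pen <- config$penalties
  eps <- fit_eps(Xm)
  eps_w <- max(Xm) * 1e-6          # W floor, see loop comment

  # Initialize at (above) the data amplitude: W ~ U(0, max X),
  # H ~ U(0, max X)/sqrt(T/3).  Starting with a reconstruction that is
  # not far below the data keeps the reconstruction-error term dominant
  # in the first multiplicative updates; initializations far below the
  # data scale let the penalty term dominate every denominator, and the
  # whole model then shrinks geometrically to zero at moderate lambda.
  set.seed(config$seed)
  mx <- max(Xm)
  W <- array(runif(N * K * L) * mx, c(N, K, L))
  H <- matrix(runif(K * T) * mx / sqrt(T / 3), K, T)

  # Cost bookkeeping is lagged by one iteration: the x-ortho cost of the
  # state reached at the end of iteration i reuses the smoothed overlap
  # that iteration i+1's H update computes anyway, so no extra
  # transpose convolution is spent on bookkeeping.
  costs <- numeric(config$max_iter)
  recon_costs <- numeric(config$max_iter)
  pen_costs <- numeric(config$max_iter)
  converged <- FALSE
  Xhat <- cpp_reconstruct(W, H)
  Z <- Xm
  n_done <- 0L

  for (iter in seq_len(config$max_iter)) {
    if (!is.null(mask))
      Z <- ifelse(mask == 1, Xm, Xhat)
    hres <- update_H_core(W, H, Z, Xhat, pen, eps)
    if (iter > 1L) {
      i <- iter - 1L
      recon_costs[i] <- sum((Xhat - Z)^2)
      pen_costs[i] <- pen$lam * hres$xortho_raw +
        cheap_penalty_value(W, H, L, pen)
      costs[i] <- recon_costs[i] + pen_costs[i]
      n_done <- i
      if (i >= 6L) {
        recent <- costs[(i - 5L):i]
        rel <- mean(abs(diff(recent))) / (abs(costs[i]) + eps)
        if (rel < config$tol) { converged <- TRUE; break }
      }
    }
    H <- hres$H
    m <- list(W = W, H = H, K = K, L = L)
    class(m) <- "factor_model"
    if (config$shift_center) m <- center_factors(m)
    # Additive floor on W before renormalization: multiplicative
    # updates cannot regrow exact zeros (centering shifts insert them,
    # and strong penalties can null whole factors before they
    # specialize), so suppressed factors are re-seeded.  Applying the
    # floor before H-renormalization scales it by each factor's
    # loading norm, so strongly suppressed factors are re-seeded only
    # weakly and winner-take-all competition is preserved.
    m$W <- m$W + eps_w
    m <- renormalize_model(m)
    W <- m$W; H <- m$H
    SH <- cpp_lag_stack(H, L)      # reused by both reconstructions
    Xhat <- cpp_reconstruct_st(W, SH)
    W <- update_W_core(W, H, Z, Xhat, pen, eps, SH = SH)
    Xhat <- cpp_reconstruct_st(W, SH)
  }

  if (!converged) {           # record the final iteration's costs
    iter <- config$max_iter
    recon_costs[iter] <- sum((Xhat - Z)^2)
    pen_costs[iter] <- penalty_cost_value(W, H, Z, L, pen)
    costs[iter] <- recon_costs[iter] + pen_costs[iter]
    n_done <- iter
  }

  if (config$final_unregularized_step) {
    pen0 <- penalty_config()
    if (!is.null(mask)) Z <- ifelse(mask == 1, Xm, Xhat)
    H <- update_H_core(W, H, Z, Xhat, pen0, eps)$H
    Xhat <- cpp_reconstruct(W, H)
    W <- update_W_core(W, H, Z, Xhat, pen0, eps)
    Xhat <- cpp_reconstruct(W, H)
  }

  model <- factor_model(W, H)
  hist <- data.frame(iteration = seq_len(n_done),
                     recon_cost = recon_costs[seq_len(n_done)],
                     penalty_cost = pen_costs[seq_len(n_done)])
  fit <- structure(list(model = model,
                        cost_history = hist,
                        rmse = sqrt(sum((Xhat - Xm)^2) / (N * T)),
                        converged = converged,
                        seed = config$seed,
                        config = config),
                   class = "cnmf_fit")
  list(fit = fit)
}

# total active penalty value at the current (W, H)
penalty_cost_value <- function(W, H, X, L, pen) {
  K <- dim(W)[2L]
  total <- cheap_penalty_value(W, H, L, pen)
  if (pen$lam > 0 && K > 1L) {
    C <- cpp_smooth_rows(cpp_transconv(W, X), L) %*% t(H)
    total <- total + pen$lam * (sum(abs(C)) - sum(abs(diag(C))))
  }
  total
}

# penalty terms that cost O(K^2 T): everything except the x-ortho term
cheap_penalty_value <- function(W, H, L, pen) {
  K <- dim(W)[2L]
  total <- 0
  if (pen$lam_ortho_h > 0 && K > 1L) {
    C <- cpp_smooth_rows(H, L) %*% t(H)
    total <- total + pen$lam_ortho_h / 2 * (sum(abs(C)) - sum(abs(diag(C))))
  }
  if (pen$lam_ortho_w > 0 && K > 1L) {
    Wflat <- apply(W, c(1L, 2L), sum)
    C <- crossprod(Wflat)
    total <- total + pen$lam_ortho_w / 2 * (sum(abs(C)) - sum(abs(diag(C))))
  }
  if (pen$lam_l1_w > 0) total <- total + pen$lam_l1_w * sum(W)
  if (pen$lam_l1_h > 0) total <- total + pen$lam_l1_h * sum(H)
  total
}

#' @export
print.cnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<cnmf_fit> K=%d, L=%d, %d iterations, rmse=%.4g, converged=%s\n",
    x$model$K, x$model$L, nrow(x$cost_history), x$rmse, x$converged))
  invisible(x)
}
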