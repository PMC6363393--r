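#' Shift the columns of a matrix, padding with zeros
#'
#' A right shift by `lag` delays the signal: column t of the output is
#' column t - lag of the input, with zeros where t - lag falls off the
#' left edge.  A left shift advances it symmetrically.  Shape is always
#' preserved; entries shifted past the edge are dropped, never wrapped.
#'
#' @param H numeric matrix (K x T).
#' @param lag integer shift, 0 <= lag < T.
#' @param direction `"right"` (delay) or `"left"` (advance).
#' @return Matrix of the same shape as `H`.
#' @examples
#' shift_cols(matrix(1:3, 1), 1, "right")  # [[0, 1, 2]]
#' @export
shift_cols <- function(H, lag, direction = c("right", "left")) {
  direction <- match.arg(direction)
  H <- as.matrix(H)
  T <- ncol(H)
  if (!is.numeric(lag) || length(lag) != 1L || lag != round(lag) || lag < 0)
    stop("shift_cols: lag must be a single nonnegative integer")
  if (lag >= T)
    stop(sprintf("shift_cols: lag %d >= T = %d shifts everything away", lag, T))
  if (lag == 0) return(H)
  out <- matrix(0, nrow(H), T)
  if (direction == "right") {
    out[, (lag + 1L):T] <- H[, 1L:(T - lag), drop = FALSE]
  } else {
    out[, 1L:(T - lag)] <- H[, (lag + 1L):T, drop = FALSE]
  }
  out
}

#' Reconstruct the data matrix from a factor model
#'
#' Computes \eqn{\tilde{X} = W \circledast H}, the sum over factors of
#' the convolution of each N x L exemplar with its temporal loadings.
#' With L = 1 this is the ordinary matrix product of the N x K slice of
#' W with H, i.e. classical NMF.
#'
#' @param model a [factor_model()].
#' @return Nonnegative N x T matrix.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  cpp_reconstruct(model$W, model$H)
}

#' Transpose tensor convolution
#'
#' \eqn{(W \circledast^\top X)_{kt} = \sum_\ell \sum_n W_{nk\ell} X_{n,t+\ell}},
#' the lagged overlap (matched-filter output) of each factor with the
#' data at every timebin; zero padded beyond the end of the recording.
#'
#' @param W N x K x L array (or N x K matrix for L = 1).
#' @param X N x T matrix or [data_matrix()].
#' @return K x T matrix of overlaps.
#' @export
transconv <- function(W, X) {
  W <- as_w_array(W)
  X <- dm_mat(X)
  if (dim(W)[1L] != nrow(X))
    stop(sprintf("transconv: W has %d channels but X has %d rows",
                 dim(W)[1L], nrow(X)))
  cpp_transconv(W, X)
}

#' Centered moving sum of each row
#'
#' Replaces each row by its moving sum over a centered square window of
#' width 2L - 1, truncated (zero padded) at the edges.  Equivalent to
#' right-multiplying by the banded T x T smoothing matrix S with
#' S_ij = 1 when |i - j| < L, but computed in O(KT) without ever
#' materializing S.
#'
#' @param A numeric matrix (K x T).
#' @param L lag count; the window width is 2L - 1.
#' @return Matrix of the same shape.
#' @export
smooth_rows <- function(A, L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  stopifnot(length(L) == 1L, L >= 1, L == round(L))
  cpp_smooth_rows(A, as.integer(L))
}

#' Squared-error reconstruction cost
#'
#' The squared Frobenius norm \eqn{\|\tilde{X} - X\|_F^2}.
#'
#' @param X data matrix or [data_matrix()].
#' @param Xhat reconstruction of the same shape.
#' @return Nonnegative scalar; zero iff the two matrices are equal.
#' @export
recon_cost <- function(X, Xhat) {
  X <- dm_mat(X); Xhat <- dm_mat(Xhat)
  if (!identical(dim(X), dim(Xhat)))
    stop("recon_cost: X and Xhat must have the same shape")
  sum((Xhat - X)^2)
}

#' Cross-orthogonality cost
#'
#' The penalty \eqn{\lambda \|(W \circledast^\top X) S H^\top\|_{1, i \ne j}}:
#' each factor's overlap with the data is smoothed in time and
#' correlated with every other factor's loadings; the absolute values of
#' all off-diagonal entries of the resulting K x K matrix are summed.
#' High values flag redundant factors that explain the same data
#' features.  For K = 1 the off-diagonal sum is empty and the cost is 0.
#'
#' @param model a [factor_model()].
#' @param X data matrix the model was fit to.
#' @param lam penalty weight \eqn{\lambda \ge 0}.
#' @return Nonnegative scalar, linear in `lam`.
#' @export
xortho_cost <- function(model, X, lam = 1) {
  stopifnot(inherits(model, "factor_model"))
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("xortho_cost: lam must be a single number >= 0")
  if (lam == 0 || model$K == 1L) return(0)
  X <- dm_mat(X)
  WtX <- cpp_transconv(model$W, X)
  C <- cpp_smooth_rows(WtX, model$L) %*% t(model$H)
  lam * (sum(abs(C)) - sum(abs(diag(C))))
}
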