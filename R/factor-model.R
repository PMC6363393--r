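#' Convolutional factor model
#'
#' Holds the exemplar tensor W (N channels x K factors x L lags) and the
#' temporal loadings H (K x T).  The model reconstruction is
#' \eqn{\tilde{X}_{nt} = \sum_k \sum_{\ell=0}^{L-1} W_{nk\ell} H_{k,t-\ell}}.
#'
#' @param W numeric 3-way array, N x K x L, entries >= 0.
#' @param H numeric matrix, K x T, entries >= 0.
#' @return An object of class `factor_model` with elements `W`, `H`,
#'   `K`, `L`.
#' @examples
#' m <- factor_model(array(1, c(2, 1, 3)), matrix(1, 1, 10))
#' m$K; m$L
#' @export
factor_model <- function(W, H) {
  W <- as_w_array(W)
  H <- as.matrix(H)
  storage.mode(H) <- "double"
  if (any(!is.finite(W)) || any(!is.finite(H)))
    stop("factor_model: W and H must be finite")
  if (any(W < 0) || any(H < 0))
    stop("factor_model: W and H must be nonnegative")
  if (dim(W)[2L] != nrow(H))
    stop(sprintf("factor_model: W has %d factors but H has %d rows",
                 dim(W)[2L], nrow(H)))
  structure(list(W = W, H = H, K = dim(W)[2L], L = dim(W)[3L]),
            class = "factor_model")
}

# internal: accept N x K x L arrays, or N x K matrices as the L = 1 case
as_w_array <- function(W) {
  if (is.matrix(W)) W <- array(W, c(nrow(W), ncol(W), 1L))
  if (!is.array(W) || length(dim(W)) != 3L)
    stop("W must be an N x K x L array")
  storage.mode(W) <- "double"
  W
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> N=%d, K=%d, L=%d, T=%d\n",
              dim(x$W)[1L], x$K, x$L, ncol(x$H)))
  invisible(x)
}
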