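#' Gaussian smoothing of each channel
#'
#' Convolves each row with a unit-area Gaussian kernel of standard
#' deviation `sd_bins` timebins (truncated at 4 SD and renormalized),
#' the standard conditioning step for raw spike trains before
#' factorization.  `sd_bins = 0` is the identity.  Edges are zero
#' padded, so mass within 4 SD of the edges is attenuated.
#'
#' @param X N x T matrix or [data_matrix()].
#' @param sd_bins kernel standard deviation in timebins, >= 0.
#' @return A [data_matrix()] of the same shape.
#' @export
gaussian_smooth <- function(X, sd_bins) {
  dm <- as_data_matrix(X)
  stopifnot(is.numeric(sd_bins), length(sd_bins) == 1L, sd_bins >= 0)
  if (sd_bins == 0) return(dm)
  half <- ceiling(4 * sd_bins)
  kern <- exp(-0.5 * ((-half):half / sd_bins)^2)
  kern <- kern / sum(kern)
  T <- ncol(dm$X)
  sm <- t(apply(dm$X, 1L, function(r) {
    padded <- c(numeric(half), r, numeric(half))
    v <- stats::filter(padded, kern, method = "convolution", sides = 2L)
    as.numeric(v[(half + 1L):(half + T)])
  }))
  sm[sm < 0] <- 0            # guard tiny negative round-off
  data_matrix(sm, channel_ids = dm$channel_ids,
              bin_seconds = dm$bin_seconds)
}

#' Divisive renormalization of calcium traces
#'
#' Divides each channel by the sum of that channel's maximum and the
#' 95th percentile of the whole matrix, so channels with large
#' transients get some priority but do not dominate the factorization.
#' Percentiles use linear interpolation between order statistics.
#' All-zero rows are left unchanged; an all-zero matrix is returned
#' unchanged with a warning.
#'
#' @param X nonnegative N x T matrix or [data_matrix()].
#' @param probs percentile of the pooled entries used in the
#'   denominator (default 0.95).
#' @return A [data_matrix()] of the same shape, row maxima <= 1.
#' @export
normalize_traces <- function(X, probs = 0.95) {
  dm <- as_data_matrix(X)
  if (all(dm$X == 0)) {
    warning("normalize_traces: X is identically zero; returned unchanged")
    return(dm)
  }
  p95 <- quantile(dm$X, probs, names = FALSE)   # type 7: linear interp
  out <- dm$X
  for (n in seq_len(nrow(out))) {
    mx <- max(out[n, ])
    if (mx > 0) out[n, ] <- out[n, ] / (mx + p95)
  }
  data_matrix(out, channel_ids = dm$channel_ids,
              bin_seconds = dm$bin_seconds)
}
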