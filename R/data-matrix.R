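#' Nonnegative data matrix container
#'
#' Wraps an N x T nonnegative matrix (channels as rows, timebins as
#' columns) together with channel labels and, optionally, the duration
#' of one timebin in seconds.  All entries must be finite and >= 0.
#'
#' @param X numeric matrix, N channels x T timebins, entries >= 0.
#' @param channel_ids optional character vector of N channel labels.
#' @param bin_seconds optional positive scalar, duration of one timebin.
#' @return An object of class `data_matrix` with elements `X`,
#'   `channel_ids`, `bin_seconds`.
#' @examples
#' dm <- data_matrix(matrix(runif(20), 4, 5))
#' dim(dm$X)
#' @export
data_matrix <- function(X, channel_ids = NULL, bin_seconds = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("data_matrix: X must have at least one row and one column")
  if (any(!is.finite(X)))
    stop("data_matrix: all entries must be finite")
  if (any(X < 0)) {
    idx <- which(X < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("data_matrix: negative entry at row %d, column %d",
                 idx[1L], idx[2L]))
  }
  if (is.null(channel_ids)) {
    channel_ids <- rownames(X)
    if (is.null(channel_ids))
      channel_ids <- paste0("ch", seq_len(nrow(X)))
  }
  if (length(channel_ids) != nrow(X))
    stop("data_matrix: channel_ids must have one label per row")
  if (!is.null(bin_seconds)) {
    stopifnot(is.numeric(bin_seconds), length(bin_seconds) == 1L,
              bin_seconds > 0)
  }
  structure(list(X = X, channel_ids = as.character(channel_ids),
                 bin_seconds = bin_seconds),
            class = "data_matrix")
}

#' Coerce to a data_matrix
#'
#' Plain matrices are wrapped; existing `data_matrix` objects pass
#' through unchanged.
#' @param x matrix or `data_matrix`.
#' @return A `data_matrix`.
#' @export
as_data_matrix <- function(x) {
  if (inherits(x, "data_matrix")) return(x)
  data_matrix(x)
}

# internal: extract the bare matrix from either representation
dm_mat <- function(x) {
  if (inherits(x, "data_matrix")) x$X else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d channels x %d timebins\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$bin_seconds))
    cat(sprintf("  bin duration: %g s\n", x$bin_seconds))
  invisible(x)
}
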