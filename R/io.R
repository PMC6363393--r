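#' Read a data matrix from delimited text
#'
#' Rows are channels, columns are timebins.  An optional header row
#' and an optional leading column of channel identifiers are honored.
#' Ragged rows, non-numeric cells and negative entries are rejected
#' with a diagnostic naming the offending position.
#'
#' @param path file to read.
#' @param delimiter field separator (default tab; `","` for CSV).
#' @param has_header `TRUE` when the first row is a header.
#' @param bin_seconds optional timebin duration stored as metadata.
#' @return A [data_matrix()].
#' @export
load_matrix <- function(path, delimiter = "\t", has_header = FALSE,
                        bin_seconds = NULL) {
  if (!file.exists(path)) stop("load_matrix: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (has_header) lines <- lines[-1L]
  if (!length(lines)) stop("load_matrix: no data rows in ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("load_matrix: ragged rows: row %d has %d fields, row 1 has %d",
                 which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]))
  first <- vapply(cells, `[[`, "", 1L)
  has_ids <- any(is.na(suppressWarnings(as.numeric(first))))
  ids <- NULL
  if (has_ids) {
    ids <- first
    cells <- lapply(cells, `[`, -1L)
  }
  X <- matrix(NA_real_, length(cells), length(cells[[1L]]))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop(sprintf("load_matrix: non-numeric cell at row %d, column %d",
                   i, which(is.na(v))[1L]))
    X[i, ] <- v
  }
  if (any(X < 0)) {
    idx <- which(X < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("load_matrix: negative entry at row %d, column %d",
                 idx[1L], idx[2L]))
  }
  data_matrix(X, channel_ids = ids, bin_seconds = bin_seconds)
}

#' Write a data matrix as delimited text
#'
#' @param X matrix or [data_matrix()].
#' @param path destination file.
#' @param delimiter field separator.
#' @param write_ids prepend each row with its channel identifier.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(X, path, delimiter = "\t", write_ids = FALSE) {
  dm <- as_data_matrix(X)
  M <- matrix(sprintf("%.17g", dm$X), nrow(dm$X))  # exact round trip
  if (write_ids) M <- cbind(dm$channel_ids, M)
  write.table(M, path, sep = delimiter, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a factor model (lossless JSON container)
#'
#' Stores W, H, dimensions, penalty settings, seed, and a format
#' version.  Numbers are serialized at full precision, so
#' save-then-load round-trips reconstruct bit-identically.
#'
#' @param model a [factor_model()] or a `cnmf_fit`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  fitobj <- NULL
  if (inherits(model, "cnmf_fit")) { fitobj <- model; model <- model$model }
  stopifnot(inherits(model, "factor_model"))
  payload <- list(
    format = "convnmf-model",
    format_version = MODEL_FORMAT_VERSION,
    software_version = as.character(packageVersion("convnmf")),
    N = dim(model$W)[1L], K = model$K, L = model$L, T = ncol(model$H),
    # %.17g round-trips IEEE doubles exactly; jsonlite's own numeric
    # formatting loses the last bit
    W = sprintf("%.17g", as.numeric(model$W)),
    H = sprintf("%.17g", as.numeric(model$H)))
  if (!is.null(fitobj)) {
    payload$penalties <- unclass(fitobj$config$penalties)
    payload$seed <- fitobj$seed
    payload$cost_history <- fitobj$cost_history
  }
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE),
             path)
  invisible(path)
}

#' Load a factor model saved by [save_model()]
#'
#' @param path file written by [save_model()].
#' @return A [factor_model()]; penalty settings, seed and cost history
#'   (when present) are attached as attribute `meta`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("load_model: file not found: ", path)
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e)
                        stop("load_model: cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (is.null(payload$format) || payload$format != "convnmf-model")
    stop("load_model: not a convnmf model file: ", path)
  if (payload$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("load_model: format version %s not supported (expected %d)",
                 payload$format_version, MODEL_FORMAT_VERSION))
  need <- c("N", "K", "L", "T", "W", "H")
  if (!all(need %in% names(payload)))
    stop("load_model: truncated or corrupt model file: ", path)
  if (length(payload$W) != payload$N * payload$K * payload$L ||
      length(payload$H) != payload$K * payload$T)
    stop("load_model: array lengths inconsistent with dimensions in ", path)
  model <- factor_model(array(as.numeric(payload$W),
                              c(payload$N, payload$K, payload$L)),
                        matrix(as.numeric(payload$H),
                               payload$K, payload$T))
  attr(model, "meta") <- payload[setdiff(names(payload), c("W", "H"))]
  model
}

#' Export a model as plain delimited text
#'
#' Writes one `factor<k>_W.tsv` file per factor (the N x L exemplar)
#' plus `H.tsv` (the K x T loadings) into a directory, for portability
#' to other tools.
#'
#' @param model a [factor_model()].
#' @param dir destination directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_model_text <- function(model, dir) {
  stopifnot(inherits(model, "factor_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- dim(model$W)[1L]
  for (k in seq_len(model$K))
    write.table(matrix(model$W[, k, ], N, model$L),
                file.path(dir, sprintf("factor%d_W.tsv", k)),
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  write.table(model$H, file.path(dir, "H.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
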