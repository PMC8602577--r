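#' Save / load a network checkpoint
#'
#' Single-file format: one line of JSON metadata (format version,
#' architecture, scaling convention, seed, and training-history summary if
#' present) terminated by a newline, followed by the parameter blocks as
#' little-endian float64 in layer order (weights then bias per layer). The
#' round-trip is lossless: loaded parameters are numerically identical and
#' [stainnet_forward()] output is unchanged.
#'
#' @param params a [stainnet()] object.
#' @param path checkpoint file path.
#' @return \code{path} invisibly; \code{load_checkpoint} returns the
#'   \code{stainnet} object.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "stainnet"))
  header <- list(format = "stainnet-checkpoint", version = 1L,
                 n_layers = params$n_layers, channels = params$channels,
                 kernel_sizes = params$kernel_sizes,
                 scaling = params$scaling, seed = params$seed,
                 history = params$history)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  for (lay in params$layers) {
    writeBin(as.numeric(lay$w), con, size = 8L, endian = "little")
    writeBin(as.numeric(lay$b), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  nl <- which(bytes == charToRaw("\n"))[1]
  if (is.na(nl)) stop("corrupt checkpoint: missing header")
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)]), simplifyVector = TRUE),
    error = function(e) stop("corrupt checkpoint: unreadable header"))
  if (!identical(header$format, "stainnet-checkpoint"))
    stop("not a stainnet checkpoint file")
  if (!identical(as.integer(header$version), 1L))
    stop("checkpoint version mismatch: ", header$version)
  net <- stainnet(header$n_layers, header$channels, seed = header$seed,
                  kernel_sizes = header$kernel_sizes)
  body <- bytes[-seq_len(nl)]
  need <- count_params(net)
  if (length(body) != need * 8L)
    stop("corrupt checkpoint: expected ", need * 8L, " parameter bytes, got ",
         length(body))
  vals <- readBin(body, "numeric", need, size = 8L, endian = "little")
  pos <- 0L
  for (l in seq_len(net$n_layers)) {
    nw <- length(net$layers[[l]]$w)
    net$layers[[l]]$w[] <- vals[pos + seq_len(nw)]; pos <- pos + nw
    nb <- length(net$layers[[l]]$b)
    net$layers[[l]]$b[] <- vals[pos + seq_len(nb)]; pos <- pos + nb
  }
  if (!is.null(header$history) && length(header$history))
    net$history <- header$history
  net
}
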