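#' Bake a network into a color lookup table
#'
#' Because an all-1x1 network maps each pixel by its color alone, the entire
#' map can be precomputed over the 256^3 input colors: applying the baked
#' table reproduces [stainnet_forward()] bit-exactly while reducing
#' whole-slide normalization to a table lookup. A subsampled table
#' (\code{stride > 1}) trades exactness for memory, applying trilinear
#' interpolation between grid nodes; its maximum observed deviation from the
#' exact forward pass (measured on 10,000 random colors at bake time) is
#' recorded in the \code{tolerance} field.
#'
#' @param params an all-1x1 [stainnet()] object (3x3 layers have a spatial
#'   receptive field and cannot be baked).
#' @param stride grid stride; 1 (default) bakes the exact full table.
#' @return an object of class \code{color_lut}.
#' @export
bake_lut <- function(params, stride = 1L) {
  stopifnot(inherits(params, "stainnet"))
  if (!all(params$kernel_sizes == 1L))
    stop("unsupported architecture: LUT baking requires all kernel sizes 1")
  stride <- as.integer(stride)
  nodes <- if (stride == 1L) 0:255 else unique(c(seq(0L, 255L, by = stride), 255L))
  nn <- length(nodes)
  lut <- matrix(0L, nn * nn * nn, 3L)
  # chunk over the blue axis to bound memory
  rg <- as.matrix(expand.grid(r = nodes, g = nodes))
  for (bi in seq_len(nn)) {
    px <- cbind(rg, b = nodes[bi])
    y <- net_forward_pixels(params, scale_in(px))
    rows <- (bi - 1L) * nn * nn + seq_len(nn * nn)
    lut[rows, ] <- as.integer(quantize_u8(scale_out(y)))
  }
  out <- structure(list(table = lut, nodes = as.integer(nodes),
                        stride = stride, tolerance = 0),
                   class = "color_lut")
  if (stride > 1L) {
    px <- with_seed(20817L, matrix(sample(0:255, 30000, replace = TRUE), ncol = 3))
    exact <- quantize_u8(scale_out(net_forward_pixels(params, scale_in(px))))
    approx <- lut_map_pixels(out, px)
    out$tolerance <- max(abs(exact - approx))
  }
  out
}

#' @export
print.color_lut <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("Color LUT: %d^3 grid (stride %d)%s\n", n, x$stride,
              if (x$stride == 1) ", exact" else
                sprintf(", max interpolation deviation %d levels", x$tolerance)))
  invisible(x)
}

# Map an N x 3 integer pixel matrix through the LUT.
lut_map_pixels <- function(lut, px) {
  n <- length(lut$nodes)
  if (lut$stride == 1L) {
    idx <- px[, 1] + 256 * px[, 2] + 65536 * px[, 3] + 1
    return(lut$table[idx, , drop = FALSE])
  }
  # trilinear interpolation on the (possibly non-uniform at the end) grid
  lo <- pmin(pmax(findInterval(px, lut$nodes), 1L), n - 1L)
  dim(lo) <- dim(px)
  x0 <- matrix(lut$nodes[lo], nrow(px)); x1 <- matrix(lut$nodes[lo + 1L], nrow(px))
  w <- (px - x0) / pmax(x1 - x0, 1L)
  acc <- matrix(0, nrow(px), 3L)
  for (dr in 0:1) for (dg in 0:1) for (db in 0:1) {
    ir <- lo[, 1] + dr; ig <- lo[, 2] + dg; ib <- lo[, 3] + db
    wt <- (if (dr == 1) w[, 1] else 1 - w[, 1]) *
          (if (dg == 1) w[, 2] else 1 - w[, 2]) *
          (if (db == 1) w[, 3] else 1 - w[, 3])
    idx <- ir + n * (ig - 1L) + n * n * (ib - 1L)
    acc <- acc + wt * lut$table[idx, , drop = FALSE]
  }
  quantize_u8(acc)
}

#' Apply a baked LUT to an image
#'
#' @param lut a [bake_lut()] result.
#' @param image an H x W x 3 RGB array (integer levels).
#' @return the mapped RGB image; bit-identical to [stainnet_forward()] of
#'   the baked network when \code{stride = 1}.
#' @export
apply_lut <- function(lut, image) {
  stopifnot(inherits(lut, "color_lut"))
  check_rgb(image)
  d <- dim(image)
  out <- lut_map_pixels(lut, flatten_pixels(image))
  storage.mode(out) <- "double"
  unflatten_pixels(out, d[1], d[2])
}

#' Save / load a LUT as a binary cube file
#'
#' Format: 8-byte magic \code{"SNLUTv1\\0"}, three int32 grid sizes, int32
#' stride, int32 tolerance, the int32 grid nodes, then the table as raw
#' bytes (R, G, B planes interleaved per entry).
#'
#' @param lut a [bake_lut()] result.
#' @param path destination file.
#' @return \code{path} invisibly; \code{load_lut} returns the LUT.
#' @export
save_lut <- function(lut, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("SNLUTv1"), con); writeBin(as.raw(0L), con)
  n <- length(lut$nodes)
  writeBin(as.integer(c(n, n, n, lut$stride, lut$tolerance)), con,
           size = 4L, endian = "little")
  writeBin(lut$nodes, con, size = 4L, endian = "little")
  writeBin(as.raw(as.integer(t(lut$table))), con)
  invisible(path)
}

#' @rdname save_lut
#' @export
load_lut <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L)[1:7])
  if (!identical(magic, "SNLUTv1")) stop("not a LUT cube file")
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  nodes <- readBin(con, "integer", hdr[1], size = 4L, endian = "little")
  nbytes <- hdr[1] * hdr[2] * hdr[3] * 3
  raw <- readBin(con, "raw", nbytes)
  if (length(raw) < nbytes) stop("corrupt LUT file: truncated table")
  tab <- matrix(as.integer(raw), ncol = 3L, byrow = TRUE)
  structure(list(table = tab, nodes = nodes, stride = hdr[4],
                 tolerance = hdr[5]), class = "color_lut")
}
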