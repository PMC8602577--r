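#' Partition image dimensions into a tile grid
#'
#' Non-overlapping half-open rectangles \code{[x0, x1) x [y0, y1)} in
#' row-major order, 0-based; the last row/column of tiles may be smaller.
#'
#' @param height,width image dimensions in pixels.
#' @param tile_size tile side length (default 512).
#' @return a data frame with columns \code{y0, y1, x0, x1}, one row per
#'   tile.
#' @export
tile_grid <- function(height, width, tile_size = 512) {
  stopifnot(height >= 1, width >= 1, tile_size >= 1)
  y0 <- seq(0L, height - 1L, by = tile_size)
  x0 <- seq(0L, width - 1L, by = tile_size)
  g <- expand.grid(x0 = x0, y0 = y0)[, 2:1]  # row-major: y outer, x inner
  data.frame(y0 = g$y0, y1 = pmin(g$y0 + tile_size, height),
             x0 = g$x0, x1 = pmin(g$x0 + tile_size, width))
}

# Is this mapper a pure per-pixel color map we can tile seamlessly?
pixelwise_mapper <- function(mapper) {
  if (inherits(mapper, "stainnet")) {
    if (!all(mapper$kernel_sizes == 1L)) return(NULL)
    return(function(tile) stainnet_forward(mapper, tile))
  }
  if (inherits(mapper, "color_lut")) return(function(tile) apply_lut(mapper, tile))
  if (inherits(mapper, "domain_shift"))
    return(function(tile) apply_domain_shift(tile, mapper))
  if (is.function(mapper) && isTRUE(attr(mapper, "pixelwise"))) return(mapper)
  NULL
}

#' Apply a pixel-wise normalizer tile by tile
#'
#' Streams over a tile grid, applying the mapper to one tile at a time, so
#' peak memory is bounded by the tile size rather than the image size.
#' Because the mapper acts on each pixel independently, the tiled output is
#' bit-identical to whole-image application for any tile size — there are no
#' seams. Mappers with a spatial receptive field (networks containing 3x3
#' layers, or functions not declaring \code{pixelwise}) are rejected.
#'
#' @param reader either an H x W x 3 array, or a function
#'   \code{f(y0, y1, x0, x1)} returning the half-open 0-based tile.
#' @param mapper a \code{stainnet} (all-1x1), \code{color_lut},
#'   \code{domain_shift}, or function with attribute \code{pixelwise = TRUE}.
#' @param writer optional function \code{f(tile, y0, y1, x0, x1)} receiving
#'   each mapped tile; when \code{NULL} and \code{reader} is an array, the
#'   assembled output image is returned.
#' @param tile_size tile side length (default 512).
#' @param height,width image dimensions; inferred when \code{reader} is an
#'   array.
#' @return the assembled image (array reader, no writer), otherwise an
#'   invisible summary list with the tile count and grid.
#' @export
normalize_tiled <- function(reader, mapper, writer = NULL, tile_size = 512,
                            height = NULL, width = NULL) {
  f <- pixelwise_mapper(mapper)
  if (is.null(f))
    stop("mapper is not pixel-wise; tiled application would create seams")
  if (is.array(reader)) {
    check_rgb(reader)
    height <- dim(reader)[1]; width <- dim(reader)[2]
    src <- reader
    reader <- function(y0, y1, x0, x1)
      src[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  } else if (is.null(height) || is.null(width)) {
    stop("height and width are required with a reader function")
  }
  grid <- tile_grid(height, width, tile_size)
  assemble <- is.null(writer)
  if (assemble) out <- array(0, c(height, width, 3L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tile <- tryCatch(reader(g$y0, g$y1, g$x0, g$x1), error = function(e)
      stop(sprintf("reader failed on tile [%d,%d)x[%d,%d): %s",
                   g$y0, g$y1, g$x0, g$x1, conditionMessage(e))))
    mapped <- f(tile)
    if (assemble) out[(g$y0 + 1):g$y1, (g$x0 + 1):g$x1, ] <- mapped
    else tryCatch(writer(mapped, g$y0, g$y1, g$x0, g$x1), error = function(e)
      stop(sprintf("writer failed on tile [%d,%d)x[%d,%d): %s",
                   g$y0, g$y1, g$x0, g$x1, conditionMessage(e))))
  }
  if (assemble) out
  else invisible(list(n_tiles = nrow(grid), tile_size = tile_size, grid = grid))
}
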