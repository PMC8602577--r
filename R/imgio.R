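#' Read an image as an 8-bit RGB array
#'
#' Reads PNG, TIFF or JPEG files into the H x W x 3 array of values in
#' \code{[0, 255]} used throughout the package. Grayscale images are promoted
#' to three equal channels with a warning; an alpha channel, if present, is
#' dropped. JPEG reading requires the \pkg{EBImage} package.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return an H x W x 3 numeric array with values in \code{[0, 255]}.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG reading requires the EBImage package")
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores images x-by-y; transpose to row (y) major
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    },
    stop("unsupported image format: .", ext)
  )
  as_rgb255(raw)
}

# Normalize a decoded [0,1] image array to H x W x 3 in [0,255].
as_rgb255 <- function(raw) {
  if (is.matrix(raw)) {
    warning("single-channel image promoted to 3-channel RGB")
    raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  } else if (length(dim(raw)) == 3L && dim(raw)[3] == 1L) {
    warning("single-channel image promoted to 3-channel RGB")
    raw <- array(rep(raw[, , 1], 3L), c(dim(raw)[1:2], 3L))
  } else if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    stop("unsupported channel layout: ", paste(dim(raw), collapse = "x"))
  }
  quantize_u8(raw * 255)
}

#' Write an 8-bit RGB array to a PNG or TIFF file
#'
#' PNG and (uncompressed baseline) TIFF round-trip losslessly through
#' [read_image()]. JPEG output is not supported.
#'
#' @param image an H x W x 3 array with values in \code{[0, 255]}.
#' @param path destination path; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  ext <- tolower(tools::file_ext(path))
  x <- image / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext)
  )
  invisible(path)
}
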