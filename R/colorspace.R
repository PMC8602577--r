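#' Convert an RGB image to optical density
#'
#' Under the Beer-Lambert law, stain absorbances add linearly in optical
#' density (OD) space, so stain separation methods operate on
#' \code{od = -log10((I + eps) / (i0 + eps))}, where \code{I} is the 8-bit
#' transmitted intensity and \code{i0} the incident (white) intensity. The
#' shared offset \code{eps} guards the logarithm at \code{I = 0} while keeping
#' \code{od = 0} exactly for white pixels and \code{od >= 0} everywhere.
#'
#' @param image an H x W x 3 array with values in \code{[0, 255]}.
#' @param i0 incident light intensity (default 255).
#' @param eps positive offset added to both numerator and denominator.
#' @return an H x W x 3 array of non-negative optical densities, with
#'   attributes \code{i0} and \code{eps}.
#' @seealso [od_to_rgb()]
#' @export
#' @examples
#' img <- array(255, c(4, 4, 3))
#' max(abs(rgb_to_od(img)))  # white tissue-free pixels have zero absorbance
rgb_to_od <- function(image, i0 = 255, eps = 1) {
  check_rgb(image)
  stopifnot(i0 > 0, eps > 0)
  od <- -log10((image + eps) / (i0 + eps))
  od[od < 0] <- 0
  attr(od, "i0") <- i0
  attr(od, "eps") <- eps
  od
}

#' Convert optical density back to an RGB image
#'
#' Inverse of [rgb_to_od()] up to 8-bit quantization:
#' \code{I = (i0 + eps) * 10^(-od) - eps}, clipped to \code{[0, 255]} and
#' rounded half to even.
#'
#' @param od an array of non-negative optical densities.
#' @param i0,eps must match the values used in [rgb_to_od()].
#' @return an RGB image array.
#' @export
od_to_rgb <- function(od, i0 = NULL, eps = NULL) {
  i0 <- i0 %||% attr(od, "i0") %||% 255
  eps <- eps %||% attr(od, "eps") %||% 1
  if (any(od < -1e-9)) stop("optical densities must be non-negative")
  out <- (i0 + eps) * 10^(-od) - eps
  out <- quantize_u8(out)
  attributes(out) <- list(dim = dim(od))
  out
}

# Ruderman et al. RGB -> LMS matrix used by Reinhard color transfer.
.lms_mat <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), nrow = 3, byrow = TRUE)
.lms_inv <- solve(.lms_mat)

# log-LMS -> lab decorrelation (orthogonal transform with 1/sqrt scaling).
.lab_mat <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), nrow = 3, byrow = TRUE)
.lab_inv <- solve(.lab_mat)

#' Convert RGB to a decorrelated lab color space
#'
#' The default space is the decorrelated log-LMS "lab" of Ruderman, the space
#' in which Reinhard-style color transfer matches channel statistics: RGB is
#' mapped to LMS cone responses, log10-transformed (with an offset of one
#' intensity level guarding log of zero), and rotated by a fixed orthogonal
#' transform into a lightness axis and two chroma axes. \code{space =
#' "cielab"} instead uses CIE L*a*b* via \code{grDevices::convertColor()}.
#'
#' @param image an H x W x 3 RGB array, values in \code{[0, 255]}.
#' @param space \code{"ruderman"} (default) or \code{"cielab"}.
#' @return an H x W x 3 array in the requested space, with a \code{space}
#'   attribute.
#' @export
rgb_to_lab <- function(image, space = c("ruderman", "cielab")) {
  space <- match.arg(space)
  check_rgb(image)
  d <- dim(image)
  px <- flatten_pixels(image)
  if (space == "ruderman") {
    lms <- px %*% t(.lms_mat)
    lab <- log10(lms + 1) %*% t(.lab_mat)
  } else {
    lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
  }
  out <- unflatten_pixels(lab, d[1], d[2])
  attr(out, "space") <- space
  out
}

#' @rdname rgb_to_lab
#' @param lab an H x W x 3 array produced by [rgb_to_lab()].
#' @export
lab_to_rgb <- function(lab, space = NULL) {
  space <- space %||% attr(lab, "space") %||% "ruderman"
  d <- dim(lab)
  px <- lab
  dim(px) <- c(d[1] * d[2], 3L)
  if (space == "ruderman") {
    lms <- 10^(px %*% t(.lab_inv)) - 1
    rgb <- lms %*% t(.lms_inv)
  } else {
    rgb <- grDevices::convertColor(px, from = "Lab", to = "sRGB") * 255
  }
  out <- quantize_u8(rgb)
  unflatten_pixels(out, d[1], d[2])
}

#' Convert RGB to grayscale luma
#'
#' Weighted luma with ITU-R BT.601 coefficients (0.299, 0.587, 0.114), the
#' convention used for the grayscale structural-similarity comparison against
#' the source image.
#'
#' @param image an H x W x 3 RGB array.
#' @param round if \code{TRUE} (default) quantize to 8-bit levels.
#' @return an H x W matrix in \code{[0, 255]}.
#' @export
rgb_to_gray <- function(image, round = TRUE) {
  check_rgb(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (round) g <- quantize_u8(g)
  g
}
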