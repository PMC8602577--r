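#' Fit Reinhard color-transfer statistics to a reference image
#'
#' Reinhard-style stain normalization matches per-channel first and second
#' moments in the decorrelated lab color space: the fit records the mean and
#' standard deviation of each lab channel over all pixels of the reference.
#'
#' @param reference an H x W x 3 RGB array with at least two distinct values
#'   per lab channel (a constant reference has zero variance and is
#'   rejected).
#' @return an object of class \code{reinhard_stats} with elements
#'   \code{mean} and \code{sd} (length-3 each).
#' @seealso [reinhard_apply()]
#' @export
reinhard_fit <- function(reference) {
  check_rgb(reference)
  lab <- flatten_lab(reference)
  m <- colMeans(lab)
  s <- apply(lab, 2, stats::sd)
  if (any(s <= 0))
    stop("degenerate reference: a lab channel has zero standard deviation")
  structure(list(mean = m, sd = s), class = "reinhard_stats")
}

flatten_lab <- function(image) {
  lab <- rgb_to_lab(image)
  d <- dim(lab)
  dim(lab) <- c(d[1] * d[2], 3L)
  lab
}

#' Apply Reinhard statistics matching to an image
#'
#' Each lab channel is standardized by the image's own moments and rescaled
#' to the reference moments: \code{out = (in - mean_src) * sd_ref / sd_src +
#' mean_ref}, then converted back to RGB, clipped and quantized. A constant
#' source channel (zero variance) falls back to substitution of the
#' reference mean.
#'
#' @param image an H x W x 3 RGB array.
#' @param stats a [reinhard_fit()] result.
#' @return the normalized RGB image.
#' @export
reinhard_apply <- function(image, stats) {
  check_rgb(image)
  stopifnot(inherits(stats, "reinhard_stats"))
  d <- dim(image)
  lab <- flatten_lab(image)
  for (ch in 1:3) {
    m <- mean(lab[, ch]); s <- stats::sd(lab[, ch])
    lab[, ch] <- if (s > 0)
      (lab[, ch] - m) * (stats$sd[ch] / s) + stats$mean[ch]
    else stats$mean[ch]
  }
  out <- unflatten_pixels(lab, d[1], d[2])
  attr(out, "space") <- "ruderman"
  lab_to_rgb(out)
}

#' @export
print.reinhard_stats <- function(x, ...) {
  cat("Reinhard lab-space reference statistics\n")
  cat("  mean:", sprintf("%.4f", x$mean), "\n")
  cat("  sd:  ", sprintf("%.4f", x$sd), "\n")
  invisible(x)
}

#' @export
predict.reinhard_stats <- function(object, image, ...) {
  reinhard_apply(image, object)
}
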