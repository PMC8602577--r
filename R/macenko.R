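# Optical-density conversion used by the stain-separation normalizers: a
# tiny eps keeps the log finite at I = 0 without biasing tissue OD.
.sep_eps <- 1e-6

sep_od_pixels <- function(image) {
  d <- dim(image)
  od <- -log10((flatten_pixels(image) + .sep_eps) / (255 + .sep_eps))
  od[od < 0] <- 0
  od
}

# Tissue mask per the Macenko convention: discard pixels whose OD is below
# beta in every channel (near-white background).
tissue_rows <- function(od, beta) {
  apply(od, 1, max) >= beta
}

#' Estimate a two-stain basis by SVD in optical-density space (Macenko)
#'
#' Tissue pixels (those with any OD channel >= \code{beta}) are projected
#' onto the plane of the two leading right-singular vectors of the OD pixel
#' matrix; the stain vectors are taken at the extreme \code{alpha_pct} and
#' \code{100 - alpha_pct} percentiles of the projection angle, yielding
#' robust estimates of the two pure-stain directions.
#'
#' @param image an H x W x 3 RGB array containing stained tissue.
#' @param beta OD threshold below which (in all channels) a pixel counts as
#'   background (default 0.15).
#' @param alpha_pct angle percentile for the robust extremes (default 1).
#' @return a 3 x 2 matrix of unit-norm, non-negative stain vectors, the more
#'   blue-absorbing (hematoxylin-like) column first.
#' @export
macenko_estimate_stains <- function(image, beta = 0.15, alpha_pct = 1.0) {
  check_rgb(image)
  od <- sep_od_pixels(image)
  od <- od[tissue_rows(od, beta), , drop = FALSE]
  if (nrow(od) < 100)
    stop("insufficient tissue: fewer than 100 pixels above the OD threshold")
  sv <- svd(od, nu = 0, nv = 3)
  if (sv$d[2] < 0.01 * sv$d[1])
    stop("degenerate basis: OD pixel cloud is effectively rank 1 (single stain)")
  v <- sv$v[, 1:2]
  proj <- od %*% v
  for (j in 1:2) if (sum(proj[, j]) < 0) { v[, j] <- -v[, j]; proj[, j] <- -proj[, j] }
  phi <- atan2(proj[, 2], proj[, 1])
  # inverted-ECDF (type 1) quantiles: invariant under duplication of the
  # pixel multiset, unlike interpolating quantile types
  lo <- stats::quantile(phi, alpha_pct / 100, names = FALSE, type = 1)
  hi <- stats::quantile(phi, 1 - alpha_pct / 100, names = FALSE, type = 1)
  s1 <- v %*% c(cos(lo), sin(lo))
  s2 <- v %*% c(cos(hi), sin(hi))
  basis <- cbind(s1, s2)
  basis[basis < 0] <- 0
  basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
  order_hematoxylin_first(basis)
}

# Hematoxylin-like column first: larger blue OD component; ties broken by
# larger red OD.
order_hematoxylin_first <- function(basis) {
  if (basis[3, 2] > basis[3, 1] + 1e-12 ||
      (abs(basis[3, 2] - basis[3, 1]) <= 1e-12 && basis[1, 2] > basis[1, 1]))
    basis <- basis[, 2:1]
  colnames(basis) <- c("hematoxylin", "eosin")
  basis
}

new_stain_profile <- function(basis, max_conc, method) {
  structure(list(basis = basis, max_conc = max_conc, method = method),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("Stain profile (%s)\n", x$method))
  print(round(x$basis, 4))
  cat("  99th-percentile concentrations:", sprintf("%.4f", x$max_conc), "\n")
  invisible(x)
}

#' Fit a Macenko stain profile to a reference image
#'
#' Estimates the reference stain basis by [macenko_estimate_stains()] and
#' records the 99th-percentile concentration of each stain as a robust
#' maximum used for concentration rescaling.
#'
#' @inheritParams macenko_estimate_stains
#' @param reference the reference RGB image.
#' @return an object of class \code{stain_profile}.
#' @export
macenko_fit <- function(reference, beta = 0.15, alpha_pct = 1.0) {
  basis <- macenko_estimate_stains(reference, beta, alpha_pct)
  conc <- stain_concentrations(sep_od_pixels(reference), basis)
  max_conc <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  if (any(max_conc <= 0)) stop("degenerate reference: zero stain concentration")
  new_stain_profile(basis, max_conc, "macenko")
}

#' Normalize an image to a Macenko stain profile
#'
#' The image's own stain basis and per-pixel nonnegative concentrations are
#' estimated; each concentration channel is rescaled so its robust maximum
#' matches the reference's, and pixels are recomposed with the reference
#' basis. Background (zero-concentration) pixels remain white.
#'
#' @param image the RGB image to normalize.
#' @param profile a [macenko_fit()] (or [vahadane_fit()]) profile.
#' @inheritParams macenko_estimate_stains
#' @return the normalized RGB image.
#' @export
macenko_apply <- function(image, profile, beta = 0.15, alpha_pct = 1.0) {
  check_rgb(image)
  stopifnot(inherits(profile, "stain_profile"))
  d <- dim(image)
  src_basis <- macenko_estimate_stains(image, beta, alpha_pct)
  recompose_with_profile(image, src_basis, profile, d)
}

# Shared by Macenko and Vahadane application: rescale concentrations to the
# reference robust maxima and recompose with the reference basis.
recompose_with_profile <- function(image, src_basis, profile, d) {
  od <- sep_od_pixels(image)
  conc <- stain_concentrations(od, src_basis)
  src_max <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  src_max[src_max <= 0] <- 1
  conc <- sweep(conc, 2, profile$max_conc / src_max, "*")
  od_new <- conc %*% t(profile$basis)
  out <- quantize_u8((255 + .sep_eps) * 10^(-od_new) - .sep_eps)
  unflatten_pixels(out, d[1], d[2])
}

#' @export
predict.stain_profile <- function(object, image, ...) {
  if (object$method == "macenko") macenko_apply(image, object)
  else vahadane_apply(image, object, ...)
}

#' Serialize / restore a stain profile as JSON
#'
#' @param profile a \code{stain_profile}.
#' @param path JSON file path.
#' @return \code{path} invisibly; \code{profile_from_json} returns the
#'   profile.
#' @export
profile_to_json <- function(profile, path) {
  jsonlite::write_json(list(method = profile$method,
                            basis = as.vector(profile$basis),
                            max_conc = profile$max_conc),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname profile_to_json
#' @export
profile_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- matrix(x$basis, 3, 2)
  colnames(basis) <- c("hematoxylin", "eosin")
  new_stain_profile(basis, x$max_conc, x$method)
}
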