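# Per-pixel nonnegative least squares against a stain basis.
#
# Concentrations must be nonnegative for the Beer-Lambert model to make
# physical sense, so an unconstrained pseudo-inverse is not used. For K <= 2
# (the only sizes used by two-stain separation) the NNLS solution has a
# closed form over the 2^K active sets, vectorized over pixels.

#' Nonnegative stain concentrations of optical-density pixels
#'
#' Solves \code{min ||basis \%*\% c - od||^2, c >= 0} independently for every
#' pixel row.
#'
#' @param od_pixels N x 3 matrix of optical densities.
#' @param basis 3 x K stain basis, K in \{1, 2\}.
#' @return N x K matrix of nonnegative concentrations.
#' @export
stain_concentrations <- function(od_pixels, basis) {
  stopifnot(is.matrix(od_pixels), ncol(od_pixels) == 3,
            is.matrix(basis), nrow(basis) == 3)
  k <- ncol(basis)
  b <- od_pixels %*% basis            # N x K cross products
  g <- crossprod(basis)               # K x K Gram matrix
  if (k == 1L) return(matrix(pmax(0, b[, 1] / g[1, 1]), ncol = 1))
  if (k != 2L) stop("closed-form NNLS implemented for K <= 2 only")
  # unconstrained solution of the 2x2 normal equations
  det <- g[1, 1] * g[2, 2] - g[1, 2]^2
  if (det <= 1e-12) stop("stain basis is rank-deficient")
  c1 <- (g[2, 2] * b[, 1] - g[1, 2] * b[, 2]) / det
  c2 <- (g[1, 1] * b[, 2] - g[1, 2] * b[, 1]) / det
  bad <- c1 < 0 | c2 < 0
  if (any(bad)) {
    # single-stain candidates; pick the one with lower objective
    a1 <- pmax(0, b[bad, 1] / g[1, 1])
    a2 <- pmax(0, b[bad, 2] / g[2, 2])
    f1 <- g[1, 1] * a1^2 - 2 * b[bad, 1] * a1
    f2 <- g[2, 2] * a2^2 - 2 * b[bad, 2] * a2
    use1 <- f1 <= f2
    c1[bad] <- ifelse(use1, a1, 0)
    c2[bad] <- ifelse(use1, 0, a2)
  }
  cbind(c1, c2, deparse.level = 0)
}

# Angle in degrees between two vectors (direction only).
angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}
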