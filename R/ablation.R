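#' Ablation network: identity color map with 3x3 smoothing layers
#'
#' Builds a 3-layer network whose color mapping is the identity but in which
#' \code{n_conv3} of the layers use a 3x3 uniform (box) spatial kernel
#' instead of 1x1. Each 3x3 layer averages its input over the local
#' neighborhood, so the network blurs exactly as much as its spatial
#' receptive field allows — a controlled probe of what replacing 1x1 with
#' 3x3 convolutions does to source-detail preservation, isolated from any
#' color change. Hidden activations are shifted by +1 so the ReLU is
#' inactive and does not distort the identity map.
#'
#' @param n_conv3 how many of the 3 layers use 3x3 kernels (0..3).
#' @return a \code{stainnet} object with 3 channels per layer.
#' @export
smoothing_stainnet <- function(n_conv3 = 0) {
  stopifnot(n_conv3 >= 0, n_conv3 <= 3)
  ks <- c(rep(3L, n_conv3), rep(1L, 3 - n_conv3))
  net <- stainnet(n_layers = 3, channels = 3, seed = 1, kernel_sizes = ks)
  for (l in 1:3) {
    k <- ks[l]
    w <- array(0, c(3, 3, k, k))
    for (ch in 1:3) w[ch, ch, , ] <- 1 / (k * k)  # box kernel, identity across channels
    net$layers[[l]]$w <- w
    net$layers[[l]]$b <- if (l == 1) rep(1, 3) else if (l == 3) rep(-1, 3) else rep(0, 3)
  }
  net
}

#' Spatial propagation radius of a single-pixel perturbation
#'
#' Applies the network to a constant mid-gray image and to a copy with one
#' center pixel changed, and reports the maximum Chebyshev distance from the
#' center at which any output pixel differs. An all-1x1 network has radius
#' 0 (the perturbation affects only its own pixel); each 3x3 layer extends
#' the receptive field by one pixel, so a network with m such layers can
#' propagate to radius m.
#'
#' @param params a \code{stainnet} object.
#' @param size side length of the probe image (odd, default 15).
#' @param value perturbed center value (default 255 on a 128 background).
#' @return integer radius (-1 if the outputs are identical everywhere).
#' @export
perturbation_radius <- function(params, size = 15, value = 255) {
  stopifnot(size %% 2 == 1, size >= 3)
  base <- array(128, c(size, size, 3))
  pert <- base
  ctr <- (size + 1) / 2
  pert[ctr, ctr, ] <- value
  d <- stainnet_forward(params, pert) != stainnet_forward(params, base)
  changed <- which(apply(d, c(1, 2), any), arr.ind = TRUE)
  if (nrow(changed) == 0) return(-1L)
  as.integer(max(pmax(abs(changed[, 1] - ctr), abs(changed[, 2] - ctr))))
}
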