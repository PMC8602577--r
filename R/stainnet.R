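#' Build a fully 1x1-convolutional color-mapping network
#'
#' The "StainNet" architecture: a stack of \code{n_layers} convolutions with
#' ReLU between all but the last, operating on RGB values scaled to
#' \code{[-1, 1]}. With all kernel sizes 1 the network is an independent
#' per-pixel color map — no output pixel depends on any neighbor — which is
#' what makes exact LUT baking and seam-free tiling possible. Kernel size 3
#' (with reflection padding) is supported for ablation studies of that
#' property. The default 3 layers x 32 channels has 1,283 parameters.
#'
#' Weights are He-uniform initialized (bound \code{sqrt(6 / fan_in)}), biases
#' zero; deterministic given \code{seed}.
#'
#' @param n_layers number of convolutional layers (>= 1, default 3).
#' @param channels hidden width (default 32).
#' @param seed integer seed for weight initialization.
#' @param kernel_sizes integer vector (recycled to \code{n_layers}) of kernel
#'   sizes, each 1 or 3.
#' @return an object of class \code{stainnet}.
#' @export
stainnet <- function(n_layers = 3, channels = 32, seed = 1, kernel_sizes = 1) {
  stopifnot(n_layers >= 1, channels >= 1)
  kernel_sizes <- rep_len(as.integer(kernel_sizes), n_layers)
  if (!all(kernel_sizes %in% c(1L, 3L)))
    stop("kernel sizes must be 1 or 3")
  dims_in <- c(3L, rep(channels, n_layers - 1))
  dims_out <- c(rep(channels, n_layers - 1), 3L)
  layers <- with_seed(seed, lapply(seq_len(n_layers), function(l) {
    k <- kernel_sizes[l]
    fan_in <- dims_in[l] * k * k
    bound <- sqrt(6 / fan_in)
    w <- array(stats::runif(dims_out[l] * dims_in[l] * k * k, -bound, bound),
               c(dims_out[l], dims_in[l], k, k))
    list(w = w, b = numeric(dims_out[l]), k = k)
  }))
  structure(list(n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 kernel_sizes = kernel_sizes, layers = layers,
                 scaling = "symmetric_unit",  # [0,255] -> [-1,1]
                 seed = as.integer(seed), history = NULL),
            class = "stainnet")
}

#' Number of parameters of a network
#'
#' Sum over layers of \code{in * out * k^2 + out}. The default 3-layer,
#' 32-channel, all-1x1 network has exactly 1,283 parameters (the compact
#' size — on the order of a thousand — that distinguishes this architecture
#' from GAN generators with millions).
#'
#' @param params a [stainnet()] object.
#' @return integer parameter count.
#' @export
count_params <- function(params) {
  stopifnot(inherits(params, "stainnet"))
  sum(vapply(params$layers, function(l) length(l$w) + length(l$b), 0))
}

# Scale conventions: 8-bit levels <-> the network's [-1, 1] working range.
scale_in <- function(x) x / 127.5 - 1
scale_out <- function(y) (y + 1) * 127.5

# Reflection padding indices (edge not repeated), PyTorch-style.
reflect_idx <- function(n) {
  if (n < 2) stop("3x3 layers require image dimensions >= 2")
  c(2L, seq_len(n), n - 1L)
}

# Forward through one layer on an H x W x Cin array in scaled space.
layer_forward <- function(a, layer) {
  d <- dim(a)
  if (layer$k == 1L) {
    x <- a; dim(x) <- c(d[1] * d[2], d[3])
    z <- x %*% t(layer$w[, , 1, 1]) + rep(layer$b, each = nrow(x))
    dim(z) <- c(d[1], d[2], length(layer$b))
    return(z)
  }
  p <- a[reflect_idx(d[1]), reflect_idx(d[2]), , drop = FALSE]
  out <- matrix(rep(layer$b, each = d[1] * d[2]), d[1] * d[2])
  for (dy in 1:3) for (dx in 1:3) {
    xs <- p[dy:(dy + d[1] - 1), dx:(dx + d[2] - 1), , drop = FALSE]
    dim(xs) <- c(d[1] * d[2], d[3])
    out <- out + xs %*% t(layer$w[, , dy, dx])
  }
  dim(out) <- c(d[1], d[2], length(layer$b))
  out
}

# Forward pass in scaled space on an H x W x 3 array; returns scaled output.
net_forward_scaled <- function(params, a) {
  nl <- params$n_layers
  for (l in seq_len(nl)) {
    a <- layer_forward(a, params$layers[[l]])
    if (l < nl) a <- pmax(a, 0)
  }
  a
}

# Forward on an N x 3 pixel matrix in scaled space (all-1x1 networks only).
net_forward_pixels <- function(params, x) {
  nl <- params$n_layers
  for (l in seq_len(nl)) {
    lay <- params$layers[[l]]
    x <- x %*% t(lay$w[, , 1, 1]) + rep(lay$b, each = nrow(x))
    if (l < nl) x <- pmax(x, 0)
  }
  x
}

#' Apply a network to an image
#'
#' Scales the image to \code{[-1, 1]}, runs the layers, rescales to
#' \code{[0, 255]}, clips and quantizes. For all-1x1 networks each output
#' pixel is a function of the matching input pixel only.
#'
#' @param params a [stainnet()] object.
#' @param image an H x W x 3 RGB array.
#' @return the mapped RGB image.
#' @export
stainnet_forward <- function(params, image) {
  stopifnot(inherits(params, "stainnet"))
  check_rgb(image)
  d <- dim(image)
  if (all(params$kernel_sizes == 1L)) {
    y <- net_forward_pixels(params, scale_in(flatten_pixels(image)))
    unflatten_pixels(quantize_u8(scale_out(y)), d[1], d[2])
  } else {
    quantize_u8(scale_out(net_forward_scaled(params, scale_in(image))))
  }
}

#' @export
#' @param object,newdata a \code{stainnet} model and the image (or list of
#'   images) to map.
#' @param ... unused.
#' @rdname stainnet_forward
predict.stainnet <- function(object, newdata, ...) {
  if (is.list(newdata)) return(lapply(newdata, stainnet_forward, params = object))
  stainnet_forward(object, newdata)
}

#' @export
print.stainnet <- function(x, ...) {
  ks <- paste(x$kernel_sizes, collapse = ",")
  cat(sprintf("StainNet color mapper: %d layers x %d channels (kernels %s), %d parameters\n",
              x$n_layers, x$channels, ks, count_params(x)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; selected epoch %d (test L1 %.5f)\n",
                length(x$history$test_loss), x$history$selected,
                min(x$history$test_loss)))
  else cat("  untrained (He-uniform initialization)\n")
  invisible(x)
}

#' @export
summary.stainnet <- function(object, ...) {
  print(object)
  for (l in seq_len(object$n_layers)) {
    lay <- object$layers[[l]]
    cat(sprintf("  layer %d: %dx%d k=%d, |w| in [%.4f, %.4f]\n", l,
                dim(lay$w)[1], dim(lay$w)[2], lay$k,
                min(abs(lay$w)), max(abs(lay$w))))
  }
  invisible(object)
}

#' @export
coef.stainnet <- function(object, ...) {
  lapply(object$layers, function(l) list(w = l$w, b = l$b))
}

#' Plot training history of a distilled network
#'
#' Train/test L1 loss (log scale) and the cosine learning-rate schedule.
#'
#' @param x a trained \code{stainnet}.
#' @param ... passed to \code{matplot}.
#' @export
plot.stainnet <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(seq_along(h$train_loss), cbind(h$train_loss, h$test_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    log = "y", xlab = "epoch", ylab = "L1 loss (scaled space)",
                    main = "distillation loss", ...)
  graphics::abline(v = h$selected, lty = 3)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::plot(seq_along(h$lr), h$lr, type = "l", xlab = "epoch",
                 ylab = "learning rate", main = "cosine schedule")
  invisible(x)
}
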