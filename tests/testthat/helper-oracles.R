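# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately scalar/naive so it cannot share a code path with the package.

rand_img <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
}

# Scalar sliding-window SSIM (uniform window, sample variances), one channel.
ssim_oracle_channel <- function(a, b, win = 7, L = 255) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- win * win
  vals <- c()
  for (i in seq_len(nrow(a) - win + 1)) {
    for (j in seq_len(ncol(a) - win + 1)) {
      wa <- as.vector(a[i:(i + win - 1), j:(j + win - 1)])
      wb <- as.vector(b[i:(i + win - 1), j:(j + win - 1)])
      ma <- mean(wa); mb <- mean(wb)
      va <- sum((wa - ma)^2) / (n - 1); vb <- sum((wb - mb)^2) / (n - 1)
      cab <- sum((wa - ma) * (wb - mb)) / (n - 1)
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                        ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

ssim_oracle <- function(a, b, win = 7) {
  if (length(dim(a)) == 3)
    mean(sapply(1:3, function(ch) ssim_oracle_channel(a[, , ch], b[, , ch], win)))
  else ssim_oracle_channel(a, b, win)
}

# Scalar forward pass of an all-1x1 network on one RGB pixel.
pixel_forward_oracle <- function(net, rgb) {
  x <- rgb / 127.5 - 1
  for (l in seq_len(net$n_layers)) {
    w <- net$layers[[l]]$w[, , 1, 1]
    z <- numeric(nrow(w))
    for (o in seq_len(nrow(w))) {
      acc <- net$layers[[l]]$b[o]
      for (i in seq_len(ncol(w))) acc <- acc + w[o, i] * x[i]
      z[o] <- acc
    }
    x <- if (l < net$n_layers) pmax(z, 0) else z
  }
  y <- round((x + 1) * 127.5)
  pmin(pmax(y, 0), 255)
}

# Scalar reference of the domain shift on one RGB pixel (mirrors the
# documented pipeline: gamma, OD mixing with a 16-level dark floor,
# range-preserving offsets).
shift_pixel_oracle <- function(rgb, shift) {
  fl <- 16
  out <- numeric(3)
  od <- numeric(3)
  for (ch in 1:3) {
    xg <- (rgb[ch] / 255)^shift$gamma[ch]
    od[ch] <- -log10((xg * 255 + fl) / (255 + fl))
  }
  for (ch in 1:3) {
    od2 <- sum(shift$mix[ch, ] * od)
    v <- 10^(-od2) * (255 + fl) - fl
    o <- shift$offset[ch]
    out[ch] <- v * (255 - abs(o)) / 255 + max(o, 0)
  }
  pmin(pmax(round(out), 0), 255)
}

angle_between <- function(a, b)
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi

# A noiseless patch with guaranteed pure-stain regions for basis recovery:
# stain 1 in the top band, stain 2 in the bottom band, white gutter between.
pure_stain_patch <- function(basis = hne_basis(), n = 60, seed = 5) {
  set.seed(seed)
  conc <- array(0, c(n, n, 2))
  conc[1:24, , 1] <- matrix(runif(24 * n, 0.2, 1.0), 24)
  conc[37:n, , 2] <- matrix(runif(24 * n, 0.2, 1.0), 24)
  cm <- conc; dim(cm) <- c(n * n, 2)
  od <- cm %*% t(basis)
  img <- pmin(pmax(round(255 * 10^(-od)), 0), 255)
  dim(img) <- c(n, n, 3)
  list(image = img, conc = conc)
}
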