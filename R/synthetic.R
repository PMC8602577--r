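#' Default hematoxylin/eosin stain basis
#'
#' Unit-norm optical-density absorbance directions for a hematoxylin-like and
#' an eosin-like stain, the standard literature values: H ~ (0.65, 0.70,
#' 0.29), E ~ (0.07, 0.99, 0.11). Columns are stains, rows are R, G, B OD
#' channels.
#'
#' @return a 3 x 2 matrix with unit-norm, non-negative columns.
#' @export
hne_basis <- function() {
  s <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(s, 2, sqrt(colSums(s^2)), "/")
}

#' Configuration for the synthetic tissue patch simulator
#'
#' Describes a stained-tissue-like scene rendered by [simulate_patch()]:
#' elliptical "nuclei" with Gaussian concentration falloff carrying stain 1
#' (hematoxylin-like) and low-concentration cytoplasm disks carrying stain 2
#' (eosin-like), composited by the Beer-Lambert law on a white background.
#'
#' @param size image side length in pixels (square patch, >= 8).
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius range (min, max) of nucleus semi-axes, pixels.
#' @param n_blobs number of cytoplasm disks.
#' @param blob_radius range of disk radii, pixels.
#' @param nucleus_conc range of peak stain-1 concentration per nucleus.
#' @param blob_conc range of stain-2 concentration per disk.
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   levels, applied after synthesis and before quantization.
#' @param basis 3 x K stain basis in OD space (unit-norm columns).
#' @param seed integer seed controlling the scene.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(size = 64, n_nuclei = 6, nucleus_radius = c(4, 9),
                         n_blobs = 4, blob_radius = c(8, 16),
                         nucleus_conc = c(0.5, 1.0), blob_conc = c(0.15, 0.4),
                         noise_sd = 3, basis = hne_basis(), seed = 1) {
  if (size < 8) stop("scene size must be >= 8")
  stopifnot(n_nuclei >= 0, n_blobs >= 0, noise_sd >= 0,
            all(nucleus_conc >= 0), all(blob_conc >= 0))
  if (any(abs(sqrt(colSums(basis^2)) - 1) > 1e-9) || any(basis < 0))
    stop("stain basis columns must be unit-norm and non-negative")
  structure(list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius, n_blobs = as.integer(n_blobs),
                 blob_radius = blob_radius, nucleus_conc = nucleus_conc,
                 blob_conc = blob_conc, noise_sd = noise_sd, basis = basis,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate a stained tissue patch
#'
#' Renders the scene described by a [scene_config()]: per-pixel stain
#' concentrations are composed into optical density through the stain basis
#' (\code{od = basis \%*\% conc}), converted to transmitted intensity
#' \code{255 * 10^(-od)}, perturbed by additive Gaussian intensity noise, then
#' clipped and quantized to 8 bits. Background pixels carry zero
#' concentration and render white. Deterministic given the config seed.
#'
#' @param config a [scene_config()].
#' @return a list with elements \code{image} (H x W x 3 RGB array) and
#'   \code{conc} (H x W x K concentration array).
#' @export
simulate_patch <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    n <- config$size
    k <- ncol(config$basis)
    conc <- array(0, c(n, n, k))
    xs <- matrix(rep(seq_len(n), each = n), n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n)  # row index
    for (i in seq_len(config$n_nuclei)) {
      cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
      a <- stats::runif(1, config$nucleus_radius[1], config$nucleus_radius[2])
      b <- stats::runif(1, config$nucleus_radius[1], config$nucleus_radius[2])
      th <- stats::runif(1, 0, pi)
      peak <- stats::runif(1, config$nucleus_conc[1], config$nucleus_conc[2])
      dx <- xs - cx; dy <- ys - cy
      u2 <- ((dx * cos(th) + dy * sin(th)) / a)^2 +
            ((-dx * sin(th) + dy * cos(th)) / b)^2
      g <- peak * exp(-2 * u2)
      g[u2 > 3.24] <- 0  # truncate the Gaussian tail: background stays zero
      conc[, , 1] <- conc[, , 1] + g
    }
    if (k >= 2) {
      for (i in seq_len(config$n_blobs)) {
        cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
        r <- stats::runif(1, config$blob_radius[1], config$blob_radius[2])
        lev <- stats::runif(1, config$blob_conc[1], config$blob_conc[2])
        d <- sqrt((xs - cx)^2 + (ys - cy)^2)
        # constant disk with a 1.5-px cosine edge ramp
        w <- pmin(pmax((r - d) / 1.5, 0), 1)
        conc[, , 2] <- conc[, , 2] + lev * (0.5 - 0.5 * cos(pi * w))
      }
    }
    cm <- conc; dim(cm) <- c(n * n, k)
    od <- cm %*% t(config$basis)
    intensity <- 255 * 10^(-od)
    if (config$noise_sd > 0)
      intensity <- intensity + stats::rnorm(length(intensity), 0, config$noise_sd)
    img <- unflatten_pixels(quantize_u8(intensity), n, n)
    list(image = img, conc = conc)
  })
}

#' A parameterized invertible cross-scanner color shift
#'
#' Models the color difference between two slide scanners as a pixel-wise,
#' invertible map: per-channel gamma on normalized intensity, a near-identity
#' 3 x 3 mixing matrix applied in optical-density space, and per-channel
#' intensity offsets. The gamma component makes the map nonlinear, so global
#' linear statistics matching cannot represent it exactly while a small
#' nonlinear per-pixel network can.
#'
#' @param gamma three positive per-channel gamma exponents.
#' @param mix invertible 3 x 3 matrix (condition number < 100) applied to the
#'   OD vector of each pixel.
#' @param offset three per-channel intensity offsets (levels), applied as a
#'   range-preserving affine step (shift plus compensating gain) so the
#'   pre-quantization map stays a bijection of the 8-bit cube. The OD
#'   conversion inside the map uses a dark floor of 16 levels, a
#'   dark-current-like term that keeps the map stably invertible near
#'   black.
#' @return an object of class \code{domain_shift}.
#' @export
domain_shift <- function(gamma = c(0.85, 1.15, 1.05),
                         mix = matrix(c(0.92, 0.05, 0.03,
                                        0.04, 0.90, 0.06,
                                        0.02, 0.05, 0.93), 3, byrow = TRUE),
                         offset = c(6, -4, 3)) {
  stopifnot(length(gamma) == 3, all(gamma > 0), length(offset) == 3,
            is.matrix(mix), all(dim(mix) == 3))
  if (!all(is.finite(mix)) || kappa(mix, exact = TRUE) >= 100)
    stop("mixing matrix must be invertible with condition number < 100")
  structure(list(gamma = gamma, mix = mix, offset = offset),
            class = "domain_shift")
}

# Shared forward/inverse core on an N x 3 intensity matrix (levels 0..255).
#
# The OD conversion uses a dark floor of 16 levels (a scanner dark-current /
# glare term): od = -log10((I + 16) / 271). Without it, one-level
# quantization of a near-black channel moves its OD by ~0.3 and leaks into
# the other channels through the mixing matrix, destroying invertibility to
# within quantization. Offsets are applied as a range-preserving affine step
# (shift toward the offset's end of the range with a compensating gain) so
# the pre-quantization map is a bijection of [0, 255]^3 into itself.
.shift_floor <- 16

shift_pixels <- function(px, shift, inverse = FALSE) {
  fl <- .shift_floor
  o <- shift$offset
  gain <- (255 - abs(o)) / 255
  if (!inverse) {
    x <- px / 255
    xg <- sweep(x, 2, shift$gamma, "^")
    od <- -log10((xg * 255 + fl) / (255 + fl))
    od2 <- od %*% t(shift$mix)
    out <- 10^(-od2) * (255 + fl) - fl
    sweep(sweep(out, 2, gain, "*"), 2, pmax(o, 0), "+")
  } else {
    y <- sweep(sweep(px, 2, pmax(o, 0), "-"), 2, gain, "/")
    tt <- pmin(pmax((y + fl) / (255 + fl), fl / (2 * (255 + fl))), 1)
    od2 <- -log10(tt)
    od <- od2 %*% t(solve(shift$mix))
    xg <- (10^(-od) * (255 + fl) - fl) / 255
    xg <- pmin(pmax(xg, 0), 1)
    sweep(xg, 2, 1 / shift$gamma, "^") * 255
  }
}

#' Apply (or invert) a cross-scanner domain shift
#'
#' Pixel-wise by construction: identical input pixels map to identical output
#' pixels, and the pre-quantization map is a bijection.
#'
#' @param image an H x W x 3 RGB array.
#' @param shift a [domain_shift()].
#' @param inverse apply the exact inverse map instead.
#' @return the shifted RGB image.
#' @export
apply_domain_shift <- function(image, shift, inverse = FALSE) {
  check_rgb(image)
  stopifnot(inherits(shift, "domain_shift"))
  d <- dim(image)
  out <- shift_pixels(flatten_pixels(image), shift, inverse = inverse)
  unflatten_pixels(quantize_u8(out), d[1], d[2])
}

#' Exact pixel-wise teacher for a known domain shift
#'
#' Returns the true source-to-target pixel map of a synthetic scanner pair as
#' a callable normalizer, usable wherever a teacher is required for
#' distillation — it plays the role an externally trained image-to-image
#' normalizer (e.g. a GAN) plays on real data, but with known ground truth.
#'
#' @param shift a [domain_shift()].
#' @param inverse if \code{TRUE}, the teacher maps target-domain images back
#'   to the source domain.
#' @return a function \code{f(image)} with attribute \code{pixelwise = TRUE}.
#' @export
oracle_teacher <- function(shift, inverse = FALSE) {
  stopifnot(inherits(shift, "domain_shift"))
  f <- function(image) apply_domain_shift(image, shift, inverse = inverse)
  attr(f, "pixelwise") <- TRUE
  class(f) <- c("pixel_mapper", "function")
  f
}

#' Generate an aligned paired dataset from the simulator
#'
#' Each pair is a simulated source patch and its domain-shifted target, so
#' pairs are perfectly registered by construction — the synthetic stand-in
#' for two scans of the same slide. A deterministic random split assigns
#' \code{round(n_pairs * test_fraction)} pairs to the test set.
#'
#' @param n_pairs number of pairs (>= 2).
#' @param scene a [scene_config()]; its seed is ignored in favor of per-pair
#'   seeds derived from \code{seed}.
#' @param shift a [domain_shift()].
#' @param test_fraction fraction of pairs held out (0 < f < 1).
#' @param seed master seed for patch generation and the split.
#' @return an object of class \code{paired_dataset}: list with \code{pairs}
#'   (list of \code{list(source, target)}), \code{split} (character vector
#'   \code{"train"}/\code{"test"}), \code{scene}, \code{shift}, \code{seed}.
#' @export
make_paired_dataset <- function(n_pairs, scene = scene_config(),
                                shift = domain_shift(), test_fraction = 0.3,
                                seed = 1) {
  stopifnot(n_pairs >= 2, test_fraction > 0, test_fraction < 1)
  n_test <- round(n_pairs * test_fraction)
  if (n_test < 1 || n_pairs - n_test < 1)
    stop("n_pairs too small to populate both train and test splits")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_pairs))
  pairs <- lapply(seeds, function(s) {
    cfg <- scene; cfg$seed <- s
    src <- simulate_patch(cfg)$image
    list(source = src, target = apply_domain_shift(src, shift))
  })
  split <- rep("train", n_pairs)
  perm <- with_seed(seed + 1L, sample.int(n_pairs))
  split[perm[seq_len(n_test)]] <- "test"
  structure(list(pairs = pairs, split = split, scene = scene, shift = shift,
                 seed = as.integer(seed)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  d <- dim(x$pairs[[1]]$source)
  cat(sprintf("Paired stain-normalization dataset: %d pairs (%d train / %d test), %dx%d px\n",
              length(x$pairs), sum(x$split == "train"), sum(x$split == "test"),
              d[1], d[2]))
  invisible(x)
}

# Pairs belonging to one split.
dataset_pairs <- function(dataset, split = c("test", "train", "all")) {
  split <- match.arg(split)
  if (split == "all") return(dataset$pairs)
  dataset$pairs[dataset$split == split]
}

#' Write / read a paired dataset as PNG directories with a JSON manifest
#'
#' The on-disk layout is \code{source/NNNN.png}, \code{target/NNNN.png} and
#' \code{manifest.json} recording the seed, split labels and shift
#' parameters.
#'
#' @param dataset a [make_paired_dataset()] result.
#' @param dir destination directory (created if needed).
#' @return \code{dir} invisibly; for \code{read_dataset}, the dataset.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_dataset"))
  dir.create(file.path(dir, "source"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "target"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$pairs)) {
    nm <- sprintf("%04d.png", i)
    write_image(dataset$pairs[[i]]$source, file.path(dir, "source", nm))
    write_image(dataset$pairs[[i]]$target, file.path(dir, "target", nm))
  }
  manifest <- list(
    n_pairs = length(dataset$pairs), seed = dataset$seed,
    split = dataset$split,
    shift = list(gamma = dataset$shift$gamma,
                 mix = as.vector(dataset$shift$mix),
                 offset = dataset$shift$offset))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  n <- man$n_pairs
  pairs <- lapply(seq_len(n), function(i) {
    nm <- sprintf("%04d.png", i)
    list(source = read_image(file.path(dir, "source", nm)),
         target = read_image(file.path(dir, "target", nm)))
  })
  shift <- domain_shift(gamma = man$shift$gamma,
                        mix = matrix(man$shift$mix, 3, 3),
                        offset = man$shift$offset)
  structure(list(pairs = pairs, split = man$split, scene = NULL,
                 shift = shift, seed = man$seed),
            class = "paired_dataset")
}
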