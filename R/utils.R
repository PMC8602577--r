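# Internal helpers shared across the package.

# Float -> 8-bit: round half to even (base round), then clip to [0, 255].
quantize_u8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "double"
  x
}

# Validate an H x W x 3 image with 8-bit value semantics.
check_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop(sprintf("`%s` must have height and width >= 1", arg), call. = FALSE)
  rng <- range(image)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` values must be finite and in [0, 255]", arg), call. = FALSE)
  invisible(image)
}

# H*W x 3 pixel matrix <-> H x W x 3 array
flatten_pixels <- function(image) {
  d <- dim(image)
  dim(image) <- c(d[1] * d[2], d[3])
  image
}

unflatten_pixels <- function(pixels, h, w) {
  k <- if (is.matrix(pixels)) ncol(pixels) else 1L
  dim(pixels) <- c(h, w, k)
  pixels
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
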