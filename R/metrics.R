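# Windowed local sums via an integral image (uniform window, valid region).
win_sum <- function(x, w) {
  h <- nrow(x); wd <- ncol(x)
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  p <- rbind(0, cbind(0, cs))
  i1 <- seq_len(h - w + 1); j1 <- seq_len(wd - w + 1)
  p[i1 + w, j1 + w, drop = FALSE] - p[i1, j1 + w, drop = FALSE] -
    p[i1 + w, j1, drop = FALSE] + p[i1, j1, drop = FALSE]
}

ssim_channel <- function(a, b, win = 7, L = 255) {
  n <- win * win
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mu_a <- win_sum(a, win) / n
  mu_b <- win_sum(b, win) / n
  # sample (n-1 denominator) variances and covariance per window
  va <- (win_sum(a * a, win) - n * mu_a^2) / (n - 1)
  vb <- (win_sum(b * b, win) - n * mu_b^2) / (n - 1)
  cab <- (win_sum(a * b, win) - n * mu_a * mu_b) / (n - 1)
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over a sliding uniform window (default 7 x 7, no Gaussian
#' weighting), with the standard stabilizing constants \code{C1 = (0.01 L)^2},
#' \code{C2 = (0.03 L)^2}, \code{L = 255}, and sample (n-1) window variances.
#' Three-channel images score the unweighted mean of per-channel SSIM.
#' Symmetric, bounded by 1, and exactly 1 for identical images.
#'
#' @param a,b images of identical shape: H x W matrices or H x W x 3 arrays
#'   with values in \code{[0, 255]}; both dimensions must be >= \code{win}.
#' @param win window side length (default 7).
#' @return SSIM value in \code{[-1, 1]}.
#' @export
ssim <- function(a, b, win = 7) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  if (length(dim(a)) == 3L) {
    return(mean(vapply(1:3, function(ch)
      ssim_channel(a[, , ch], b[, , ch], win), 0)))
  }
  ssim_channel(a, b, win)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' \code{10 * log10(255^2 / MSE)} in dB for 8-bit images. Identical images
#' have zero MSE and return the sentinel \code{Inf}.
#'
#' @param a,b images of identical shape, values in \code{[0, 255]}.
#' @return PSNR in dB (\code{Inf} for identical inputs).
#' @export
psnr <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Evaluate a normalizer over the test split of a paired dataset
#'
#' For every (source, target) pair the normalizer output is scored three
#' ways: SSIM and PSNR against the target in RGB (similarity to the target
#' style), and SSIM of the grayscale output against the grayscale source
#' (preservation of source structure). Results are aggregated as mean and
#' sample (n-1) standard deviation. Pairs with infinite PSNR (bit-identical
#' output and target) are excluded from the PSNR aggregate and counted in
#' \code{n_psnr_inf}; pairs on which the normalizer errors are excluded from
#' everything and counted in \code{n_failed}.
#'
#' @param normalizer a function mapping an RGB image to an RGB image.
#' @param dataset a [make_paired_dataset()] result.
#' @param split which split to evaluate (default \code{"test"}).
#' @param method label for the output row.
#' @return a one-row data frame with columns \code{method},
#'   \code{ssim_target_mean/sd}, \code{psnr_target_mean/sd},
#'   \code{ssim_source_mean/sd}, \code{n_pairs}, \code{n_psnr_inf},
#'   \code{n_failed}.
#' @export
evaluate_pairs <- function(normalizer, dataset, split = "test",
                           method = "normalizer") {
  pairs <- dataset_pairs(dataset, split)
  if (length(pairs) == 0) stop("empty evaluation split")
  st <- pt <- ss <- rep(NA_real_, length(pairs))
  failed <- 0L
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    out <- tryCatch(normalizer(p$source), error = function(e) NULL)
    if (is.null(out)) { failed <- failed + 1L; next }
    st[i] <- ssim(out, p$target)
    pt[i] <- psnr(out, p$target)
    ss[i] <- ssim(rgb_to_gray(out), rgb_to_gray(p$source))
  }
  ok <- !is.na(st)
  pfin <- pt[ok][is.finite(pt[ok])]
  data.frame(method = method,
             ssim_target_mean = mean(st[ok]), ssim_target_sd = stats::sd(st[ok]),
             psnr_target_mean = mean(pfin), psnr_target_sd = stats::sd(pfin),
             ssim_source_mean = mean(ss[ok]), ssim_source_sd = stats::sd(ss[ok]),
             n_pairs = sum(ok), n_psnr_inf = sum(is.infinite(pt[ok])),
             n_failed = failed, stringsAsFactors = FALSE)
}

#' Compare normalization methods on one paired dataset
#'
#' Builds each requested normalizer (classical methods are fitted to the
#' given reference image; \code{"stainnet"} uses the supplied trained model;
#' \code{"oracle"} uses the dataset's own generating shift) and scores it
#' with [evaluate_pairs()], one row per method in the order requested.
#'
#' @param dataset a [make_paired_dataset()] result.
#' @param methods character vector from \code{"reinhard"}, \code{"macenko"},
#'   \code{"vahadane"}, \code{"stainnet"}, \code{"oracle"}.
#' @param reference RGB reference image, required for the classical methods.
#' @param checkpoint trained [stainnet()] model, required for
#'   \code{"stainnet"}.
#' @param split split to evaluate.
#' @return a data frame, one row per method (CSV-ready).
#' @export
compare_methods <- function(dataset, methods, reference = NULL,
                            checkpoint = NULL, split = "test") {
  build <- function(m) {
    switch(m,
      reinhard = {
        if (is.null(reference)) stop("method 'reinhard' needs a reference image")
        stats <- reinhard_fit(reference)
        function(img) reinhard_apply(img, stats)
      },
      macenko = {
        if (is.null(reference)) stop("method 'macenko' needs a reference image")
        prof <- macenko_fit(reference)
        function(img) macenko_apply(img, prof)
      },
      vahadane = {
        if (is.null(reference)) stop("method 'vahadane' needs a reference image")
        prof <- vahadane_fit(reference)
        function(img) vahadane_apply(img, prof)
      },
      stainnet = {
        if (is.null(checkpoint)) stop("method 'stainnet' needs a trained model")
        function(img) stainnet_forward(checkpoint, img)
      },
      oracle = {
        if (is.null(dataset$shift)) stop("dataset carries no generating shift")
        oracle_teacher(dataset$shift)
      },
      stop("unknown method: ", m))
  }
  rows <- lapply(methods, function(m) {
    f <- build(m)  # force construction so missing inputs fail loudly
    evaluate_pairs(f, dataset, split = split, method = m)
  })
  do.call(rbind, rows)
}
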