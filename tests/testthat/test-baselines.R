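test_that("reinhard statistics match a scalar oracle and reject degenerate refs", {
  img <- rand_img(12, 12, seed = 21)
  st <- reinhard_fit(img)
  lab <- rgb_to_lab(img)
  for (ch in 1:3) {
    vals <- as.vector(lab[, , ch])
    m <- sum(vals) / length(vals)
    s <- sqrt(sum((vals - m)^2) / (length(vals) - 1))
    expect_equal(st$mean[[ch]], m, tolerance = 1e-12)
    expect_equal(st$sd[[ch]], s, tolerance = 1e-12)
  }
  # set statistics: invariant to pixel permutation
  set.seed(22); perm <- sample(144)
  shuffled <- array(matrix(img, 144, 3)[perm, ], dim(img))
  st2 <- reinhard_fit(shuffled)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)
  expect_error(reinhard_fit(array(100, c(8, 8, 3))), "degenerate")
})

test_that("reinhard matching reproduces the reference moments", {
  # Moment matching is exact before 8-bit quantization; quantization is the
  # only deviation when no pixel leaves the RGB gamut, which holds when
  # source and reference share a color distribution. Mean errors are scored
  # against the channel spread since the chroma means sit near zero.
  set.seed(30)
  for (t in 1:3) {
    ref <- array(as.numeric(sample(0:255, 48 * 48 * 3, TRUE)), c(48, 48, 3))
    img <- array(as.numeric(sample(0:255, 48 * 48 * 3, TRUE)), c(48, 48, 3))
    st <- reinhard_fit(ref)
    lab <- rgb_to_lab(reinhard_apply(img, st))
    for (ch in 1:3) {
      expect_lt(abs(mean(lab[, , ch]) - st$mean[ch]) / st$sd[ch], 0.005)
      expect_lt(abs(sd(as.vector(lab[, , ch])) - st$sd[ch]) / st$sd[ch], 0.005)
    }
  }
  # an image already at the reference statistics passes through unchanged
  ref <- simulate_patch(scene_config(size = 48, seed = 31))$image
  st <- reinhard_fit(ref)
  self <- reinhard_apply(ref, st)
  expect_lte(max(abs(self - ref)), 1)
  # constant image maps to the reference mean color
  out_const <- reinhard_apply(array(120, c(8, 8, 3)), st)
  expect_length(unique(matrix(out_const, 64, 3)[, 1]), 1)
  mean_rgb <- lab_to_rgb(array(rep(st$mean, each = 1), c(1, 1, 3)))
  expect_equal(out_const[1, 1, ], as.vector(mean_rgb))
})

test_that("macenko recovers a known stain basis within 1 degree", {
  truth <- hne_basis()
  patch <- pure_stain_patch(truth)
  est <- macenko_estimate_stains(patch$image)
  expect_lt(angle_between(est[, 1], truth[, 1]), 1)
  expect_lt(angle_between(est[, 2], truth[, 2]), 1)
  # hematoxylin-like column (larger blue OD) comes first
  expect_gt(est[3, 1], est[3, 2])
  # set statistic: invariant to shuffling and duplication
  set.seed(23); perm <- sample(3600)
  shuffled <- array(matrix(patch$image, 3600, 3)[perm, ], dim(patch$image))
  expect_equal(macenko_estimate_stains(shuffled), est)
  doubled <- array(0, c(60, 120, 3))
  doubled[, 1:60, ] <- patch$image; doubled[, 61:120, ] <- patch$image
  expect_equal(macenko_estimate_stains(doubled), est)
  expect_error(macenko_estimate_stains(array(255, c(32, 32, 3))),
               "insufficient tissue")
})

test_that("macenko normalization is a near-identity on its own reference", {
  ref <- pure_stain_patch(seed = 41)$image
  prof <- macenko_fit(ref)
  out <- macenko_apply(ref, prof)
  expect_lte(max(abs(out - ref)), 2)
  # white background pixels stay white
  img <- pure_stain_patch(seed = 43)$image
  out2 <- macenko_apply(img, prof)
  white <- img[, , 1] == 255 & img[, , 2] == 255 & img[, , 3] == 255
  for (ch in 1:3) expect_gte(min(out2[, , ch][white]), 253)
})

test_that("macenko maps a source basis onto the reference basis", {
  s1 <- hne_basis()
  s2 <- cbind(c(0.55, 0.75, 0.36), c(0.15, 0.95, 0.20))
  s2 <- sweep(s2, 2, sqrt(colSums(s2^2)), "/")
  src <- pure_stain_patch(s1, seed = 44)$image
  ref <- pure_stain_patch(s2, seed = 45)$image
  out <- macenko_apply(src, macenko_fit(ref))
  est <- macenko_estimate_stains(out)
  expect_lt(angle_between(est[, 1], s2[, 1]), 2)
  expect_lt(angle_between(est[, 2], s2[, 2]), 2)
})

test_that("normalization output depends on the reference image", {
  img <- simulate_patch(scene_config(size = 32, seed = 51))$image
  ref1 <- simulate_patch(scene_config(size = 32, seed = 52))$image
  ref2 <- apply_domain_shift(ref1, domain_shift())
  out1 <- reinhard_apply(img, reinhard_fit(ref1))
  out2 <- reinhard_apply(img, reinhard_fit(ref2))
  expect_gt(mean(abs(out1 - out2)), 1)
})
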