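test_that("empty noiseless scene renders pure white; simulation is deterministic", {
  cfg <- scene_config(size = 16, n_nuclei = 0, n_blobs = 0, noise_sd = 0)
  p <- simulate_patch(cfg)
  expect_equal(unique(as.vector(p$image)), 255)
  expect_equal(max(p$conc), 0)
  cfg2 <- scene_config(size = 32, seed = 42)
  expect_identical(simulate_patch(cfg2), simulate_patch(cfg2))
  expect_error(scene_config(size = 4), ">= 8")
})

test_that("noiseless patches obey the Beer-Lambert closed form per pixel", {
  cfg <- scene_config(size = 24, noise_sd = 0, seed = 13)
  p <- simulate_patch(cfg)
  s <- cfg$basis
  for (idx in list(c(3, 7), c(12, 12), c(20, 5), c(24, 24))) {
    cvec <- p$conc[idx[1], idx[2], ]
    od <- as.vector(s %*% cvec)
    expect_equal(p$image[idx[1], idx[2], ],
                 pmin(pmax(round(255 * 10^(-od)), 0), 255))
  }
})

test_that("concentrations are recoverable from noiseless patches by NNLS", {
  # Quantization-limited recovery needs pixels that are not too dark (one
  # intensity level perturbs OD by ~0.5/I), so the scene avoids heavy
  # nucleus overlap.
  for (s in c(17, 18, 19)) {
    cfg <- scene_config(size = 40, n_nuclei = 4, n_blobs = 3, noise_sd = 0,
                        seed = s)
    p <- simulate_patch(cfg)
    od <- -log10((matrix(p$image, 40 * 40, 3) + 1e-9) / 255)
    od[od < 0] <- 0
    rec <- stain_concentrations(od, cfg$basis)
    truth <- p$conc; dim(truth) <- c(40 * 40, 2)
    expect_lte(max(abs(rec - truth)), 0.02)
  }
})

test_that("domain shift is an identity for the identity parameters and pointwise", {
  ident <- domain_shift(gamma = c(1, 1, 1), mix = diag(3), offset = c(0, 0, 0))
  img <- rand_img(10, 10, seed = 6)
  expect_equal(apply_domain_shift(img, ident), img)
  const <- array(87, c(5, 5, 3))
  sh <- domain_shift()
  out <- apply_domain_shift(const, sh)
  expect_length(unique(matrix(out, 25, 3)[, 1]), 1)
  # shuffling pixels commutes with the shift
  set.seed(2)
  perm <- sample(100)
  shuffle <- function(x) { px <- matrix(x, 100, 3)[perm, ]; array(px, dim(x)) }
  expect_equal(apply_domain_shift(shuffle(img), sh),
               shuffle(apply_domain_shift(img, sh)))
  expect_error(domain_shift(mix = matrix(1, 3, 3)), "invertible")
})

test_that("domain shift matches the scalar per-pixel reference", {
  sh <- domain_shift(gamma = c(0.8, 1.2, 1.1),
                     mix = matrix(c(0.9, 0.07, 0.03,
                                    0.05, 0.88, 0.07,
                                    0.04, 0.06, 0.9), 3, byrow = TRUE),
                     offset = c(-5, 8, 0))
  img <- rand_img(2, 2, seed = 8)
  out <- apply_domain_shift(img, sh)
  for (i in 1:2) for (j in 1:2)
    expect_equal(out[i, j, ], shift_pixel_oracle(img[i, j, ], sh))
})

test_that("oracle teacher is the shift map and its inverse round-trips", {
  sh <- domain_shift()
  img <- rand_img(12, 12, seed = 10)
  expect_identical(oracle_teacher(sh)(img), apply_domain_shift(img, sh))
  inv <- oracle_teacher(sh, inverse = TRUE)
  expect_lte(max(abs(inv(apply_domain_shift(img, sh)) - img)), 2)
  ident <- domain_shift(gamma = c(1, 1, 1), mix = diag(3), offset = c(0, 0, 0))
  expect_equal(oracle_teacher(ident)(img), img)
})

test_that("paired datasets split deterministically and pairs are consistent", {
  scn <- scene_config(size = 16)
  ds <- make_paired_dataset(10, scn, test_fraction = 0.3, seed = 3)
  expect_equal(sum(ds$split == "train"), 7)
  expect_equal(sum(ds$split == "test"), 3)
  for (p in ds$pairs)
    expect_identical(p$target, apply_domain_shift(p$source, ds$shift))
  expect_identical(make_paired_dataset(10, scn, test_fraction = 0.3, seed = 3), ds)
  ds2 <- make_paired_dataset(10, scn, test_fraction = 0.3, seed = 4)
  expect_false(identical(ds2$pairs[[1]]$source, ds$pairs[[1]]$source))
  expect_error(make_paired_dataset(2, scn, test_fraction = 0.05), "too small")
})

test_that("datasets round-trip through the PNG directory layout", {
  dir <- withr::local_tempdir()
  ds <- make_paired_dataset(4, scene_config(size = 16), test_fraction = 0.25,
                            seed = 5)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$split, ds$split)
  for (i in seq_along(ds$pairs)) {
    expect_equal(back$pairs[[i]]$source, ds$pairs[[i]]$source)
    expect_equal(back$pairs[[i]]$target, ds$pairs[[i]]$target)
  }
})
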