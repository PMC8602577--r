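# Enumeration oracle: count every scalar in the weight/bias arrays.
enumerate_params <- function(net) {
  total <- 0L
  for (lay in net$layers) total <- total + length(lay$w) + length(lay$b)
  total
}

test_that("parameter counts match the enumeration oracle", {
  cases <- list(
    list(net = stainnet(n_layers = 1), expected = 12),
    list(net = stainnet(n_layers = 3, channels = 8), expected = 131),
    list(net = stainnet(), expected = 1283),
    list(net = stainnet(kernel_sizes = c(3, 3, 3)), expected = 11011)
  )
  for (cs in cases) {
    expect_equal(count_params(cs$net), cs$expected)
    expect_equal(count_params(cs$net), enumerate_params(cs$net))
  }
  expect_error(stainnet(kernel_sizes = 5), "kernel")
})

test_that("initialization is deterministic given the seed", {
  expect_identical(stainnet(seed = 7), stainnet(seed = 7))
  expect_false(identical(stainnet(seed = 7), stainnet(seed = 8)))
  net <- stainnet(seed = 7)
  expect_true(all(vapply(net$layers, function(l) all(l$b == 0), TRUE)))
})

test_that("forward pass: zero network is constant 128, pixels are independent", {
  net <- stainnet(n_layers = 3, channels = 4)
  zero <- net
  for (l in 1:3) { zero$layers[[l]]$w[] <- 0; zero$layers[[l]]$b[] <- 0 }
  img <- rand_img(6, 6, seed = 71)
  expect_equal(unique(as.vector(stainnet_forward(zero, img))), 128)
  # shuffle commutes for all-1x1 networks
  set.seed(72); perm <- sample(36)
  shuffle <- function(x) array(matrix(x, 36, 3)[perm, ], dim(x))
  expect_equal(stainnet_forward(net, shuffle(img)),
               shuffle(stainnet_forward(net, img)))
})

test_that("forward pass matches the scalar per-pixel oracle", {
  net <- stainnet(n_layers = 3, channels = 5, seed = 73)
  img <- rand_img(4, 4, seed = 74)
  out <- stainnet_forward(net, img)
  for (i in 1:4) for (j in 1:4)
    expect_equal(out[i, j, ], pixel_forward_oracle(net, img[i, j, ]))
})

test_that("single-pixel perturbations stay local for 1x1, spread for 3x3", {
  net1 <- stainnet(seed = 75)
  img <- rand_img(9, 9, seed = 76)
  pert <- img; pert[5, 5, ] <- (pert[5, 5, ] + 101) %% 256
  d <- stainnet_forward(net1, pert) != stainnet_forward(net1, img)
  changed <- which(apply(d, c(1, 2), any), arr.ind = TRUE)
  expect_true(nrow(changed) <= 1)
  if (nrow(changed) == 1) expect_equal(unname(changed[1, ]), c(5L, 5L))
  expect_equal(perturbation_radius(net1), 0L)
  # dependence radius equals the number of 3x3 layers
  for (m in 1:3)
    expect_equal(perturbation_radius(smoothing_stainnet(m)), m)
})

test_that("3x3 layers apply reflection-padded convolution", {
  net <- stainnet(n_layers = 1, kernel_sizes = 3, seed = 83)
  img <- rand_img(5, 6, seed = 84)
  out <- stainnet_forward(net, img)
  w <- net$layers[[1]]$w; b <- net$layers[[1]]$b
  x <- img / 127.5 - 1
  ridx <- function(n) c(2, 1:n, n - 1)
  xp <- x[ridx(5), ridx(6), ]
  for (i in 1:5) for (j in 1:6) {
    z <- b
    for (o in 1:3) for (ci in 1:3) for (dy in 1:3) for (dx in 1:3)
      z[o] <- z[o] + w[o, ci, dy, dx] * xp[i + dy - 1, j + dx - 1, ci]
    expect_equal(out[i, j, ], pmin(pmax(round((z + 1) * 127.5), 0), 255))
  }
})

test_that("checkpoints round-trip losslessly and detect corruption", {
  net <- stainnet(seed = 77)
  net$history <- list(train_loss = c(0.5, 0.2), test_loss = c(0.6, 0.3),
                      lr = c(0.01, 0.005), selected = 2L)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  for (l in 1:3) {
    expect_identical(back$layers[[l]]$w, net$layers[[l]]$w)
    expect_identical(back$layers[[l]]$b, net$layers[[l]]$b)
  }
  img <- rand_img(8, 8, seed = 78)
  expect_identical(stainnet_forward(back, img), stainnet_forward(net, img))
  # truncation is detected
  bytes <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".ckpt")
  writeBin(bytes[1:(length(bytes) - 100)], trunc_path)
  expect_error(load_checkpoint(trunc_path), "corrupt")
  garbage <- withr::local_tempfile(fileext = ".ckpt")
  writeBin(charToRaw("not a checkpoint\nmore"), garbage)
  expect_error(load_checkpoint(garbage))
})

test_that("strided LUTs honor their recorded interpolation tolerance", {
  net <- stainnet(seed = 79)
  lut <- bake_lut(net, stride = 8)
  expect_gt(length(lut$nodes), 30)
  img <- rand_img(20, 20, seed = 80)
  dev <- max(abs(apply_lut(lut, img) - stainnet_forward(net, img)))
  expect_lte(dev, lut$tolerance + 2)
  # LUT undefined for networks with a spatial receptive field
  expect_error(bake_lut(stainnet(kernel_sizes = c(1, 3, 1))), "unsupported")
  path <- withr::local_tempfile(fileext = ".cube")
  save_lut(lut, path)
  back <- load_lut(path)
  expect_equal(back$table, lut$table)
  expect_identical(apply_lut(back, img), apply_lut(lut, img))
})

test_that("model methods print, summarize and expose coefficients", {
  net <- stainnet(seed = 81)
  expect_output(print(net), "1283 parameters")
  expect_output(summary(net), "layer 3")
  cf <- coef(net)
  expect_length(cf, 3)
  expect_equal(dim(cf[[1]]$w), c(32L, 3L, 1L, 1L))
  img <- rand_img(5, 5, seed = 82)
  expect_identical(predict(net, img), stainnet_forward(net, img))
})
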