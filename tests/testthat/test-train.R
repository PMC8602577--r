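test_that("cosine schedule runs from initial_lr to exactly zero", {
  cfg <- train_config(initial_lr = 0.01, epochs = 300)
  expect_identical(cosine_lr(0, cfg), 0.01)
  expect_identical(cosine_lr(300, cfg), 0.01 * 0.5 * (1 + cos(pi)))
  expect_equal(cosine_lr(300, cfg), 0)
  expect_equal(cosine_lr(150, cfg), 0.005)
  lrs <- vapply(0:300, cosine_lr, 0, config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(301, cfg), "range")
})

test_that("L1 loss is the mean absolute difference", {
  a <- rand_img(6, 6, seed = 91)
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(a, pmin(a + 2, 257)), 2)
  b <- rand_img(6, 6, seed = 92)
  # scalar-loop oracle
  acc <- 0
  for (i in 1:6) for (j in 1:6) for (ch in 1:3)
    acc <- acc + abs(a[i, j, ch] - b[i, j, ch])
  expect_equal(l1_loss(a, b), acc / (6 * 6 * 3))
  expect_error(l1_loss(a, a[1:3, , , drop = FALSE]), "shape")
})

test_that("analytic gradients match central finite differences", {
  net <- stainnet(n_layers = 3, channels = 4, seed = 93)
  set.seed(94)
  # randomize biases so no pre-activation sits exactly on the ReLU kink
  # (freshly built networks have all-zero biases, which parks dead samples
  # right at z = 0), and offset the targets so |pred - target| stays away
  # from the L1 kink: central differences then probe a smooth region
  for (l in 1:3) net$layers[[l]]$b <- runif(length(net$layers[[l]]$b), -0.3, 0.3)
  x <- matrix(runif(30, -1, 1), 10, 3)
  y <- stainnorm:::net_forward_pixels(net, x) - 0.7
  lg <- stainnorm:::net_loss_grad(net, x, y)
  loss_at <- function(net) stainnorm:::net_loss_grad(net, x, y)$loss
  h <- 1e-6
  worst <- 0
  for (l in 1:3) {
    w <- net$layers[[l]]$w
    set.seed(95 + l)
    picks <- sample(length(w), min(6, length(w)))
    for (p in picks) {
      np <- net; np$layers[[l]]$w[p] <- w[p] + h
      nm <- net; nm$layers[[l]]$w[p] <- w[p] - h
      fd <- (loss_at(np) - loss_at(nm)) / (2 * h)
      an <- as.vector(lg$grads[[l]]$w)[p]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
    for (p in seq_along(net$layers[[l]]$b)) {
      np <- net; np$layers[[l]]$b[p] <- np$layers[[l]]$b[p] + h
      nm <- net; nm$layers[[l]]$b[p] <- nm$layers[[l]]$b[p] - h
      fd <- (loss_at(np) - loss_at(nm)) / (2 * h)
      worst <- max(worst, abs(fd - lg$grads[[l]]$b[p]) /
                            max(abs(fd), abs(lg$grads[[l]]$b[p]), 1e-8))
    }
  }
  expect_lt(worst, 1e-4)
})

small_identity_dataset <- function(n = 8, size = 16, seed = 96) {
  imgs <- lapply(seq_len(n), function(i)
    simulate_patch(scene_config(size = size, seed = seed + i))$image)
  pairs <- lapply(imgs, function(im) list(source = im, target = im))
  structure(list(pairs = pairs,
                 split = rep(c("train", "test"), c(n - 2, 2)),
                 scene = NULL, shift = NULL, seed = seed),
            class = "paired_dataset")
}

test_that("training reduces loss, is deterministic, and returns the best epoch", {
  ds <- small_identity_dataset()
  cfg <- train_config(epochs = 12, batch_size = 2, seed = 5)
  net0 <- stainnet(channels = 8, seed = 5)
  fit <- train_stainnet(net0, ds, cfg)
  h <- fit$history
  expect_length(h$test_loss, 12)
  expect_lt(h$test_loss[12], h$test_loss[1])
  expect_equal(h$selected, which.min(h$test_loss))
  expect_equal(h$lr, vapply(0:11, cosine_lr, 0, config = cfg))
  # determinism: bit-identical history and weights
  fit2 <- train_stainnet(stainnet(channels = 8, seed = 5), ds, cfg)
  expect_identical(fit2$history, h)
  expect_identical(fit2$layers, fit$layers)
  # the returned weights reproduce the recorded minimum test loss
  te <- ds$pairs[ds$split == "test"]
  relosses <- vapply(te, function(p) {
    x <- matrix(p$source, 256, 3) / 127.5 - 1
    y <- matrix(p$target, 256, 3) / 127.5 - 1
    mean(abs(stainnorm:::net_forward_pixels(fit, x) - y))
  }, 0)
  expect_equal(mean(relosses), min(h$test_loss), tolerance = 1e-12)
})

test_that("distilling a pixel-wise teacher recovers its map on held-out images", {
  shift <- domain_shift()
  imgs <- lapply(1:100, function(i)
    simulate_patch(scene_config(size = 32, seed = 200 + i))$image)
  teacher <- oracle_teacher(shift)
  cfg <- train_config(epochs = 120, seed = 3)
  fit <- distill(teacher, imgs, cfg, channels = 32)
  held <- lapply(301:304, function(s)
    simulate_patch(scene_config(size = 32, seed = s))$image)
  mae <- mean(vapply(held, function(im)
    mean(abs(stainnet_forward(fit, im) - teacher(im))), 0))
  expect_lte(mae, 3)
})

test_that("a content-dependent teacher leaves an irreducible training loss", {
  ref <- simulate_patch(scene_config(size = 32, seed = 400))$image
  st <- reinhard_fit(ref)
  teacher <- function(img) reinhard_apply(img, st)
  imgs <- lapply(1:12, function(i)
    simulate_patch(scene_config(size = 24, seed = 410 + i))$image)
  fit <- distill(teacher, imgs, train_config(epochs = 25, batch_size = 4,
                                             seed = 2), channels = 8)
  # Reinhard standardizes by each image's own statistics, so no single
  # pixel map fits all pairs: the train loss plateaus above zero
  expect_gt(min(fit$history$train_loss), 1e-3)
})

test_that("teacher failures abort with the offending image index", {
  bad_teacher <- function(img) stop("boom")
  imgs <- list(rand_img(8, 8, 1), rand_img(8, 8, 2))
  expect_error(distill(bad_teacher, imgs, train_config(epochs = 1)),
               "source image 1")
})
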