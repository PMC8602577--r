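#' Training configuration for distillation
#'
#' Defaults follow the published recipe: plain SGD, initial learning rate
#' 0.01 decayed to 0 by cosine annealing over 300 epochs, batch size 10
#' images, L1 loss, and selection of the epoch with the lowest test loss.
#' Momentum and weight decay are available but default to off.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param epochs number of epochs (>= 1).
#' @param batch_size images per mini-batch (>= 1).
#' @param seed seed controlling shuffling (training is fully deterministic
#'   given it).
#' @param momentum SGD momentum (default 0).
#' @param weight_decay L2 penalty coefficient (default 0).
#' @param pixel_subsample optional number of random pixels drawn per image
#'   per batch instead of using every pixel; unbiased for the expected
#'   gradient since the network is pixel-wise.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(initial_lr = 0.01, epochs = 300, batch_size = 10,
                         seed = 1, momentum = 0, weight_decay = 0,
                         pixel_subsample = NULL) {
  stopifnot(initial_lr > 0, epochs >= 1, batch_size >= 1,
            momentum >= 0, weight_decay >= 0)
  structure(list(initial_lr = initial_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 momentum = momentum, weight_decay = weight_decay,
                 pixel_subsample = pixel_subsample),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' \code{lr(epoch) = 0.5 * initial_lr * (1 + cos(pi * epoch / epochs))}:
#' exactly \code{initial_lr} at epoch 0, exactly 0 at \code{epoch = epochs},
#' monotone non-increasing in between.
#'
#' @param epoch epoch index in \code{[0, epochs]}.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
cosine_lr <- function(epoch, config) {
  if (any(epoch < 0 | epoch > config$epochs))
    stop("epoch out of range [0, epochs]")
  0.5 * config$initial_lr * (1 + cos(pi * epoch / config$epochs))
}

#' Mean absolute (L1) loss
#'
#' @param pred,target arrays of identical shape.
#' @return mean absolute difference over all entries.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("shape mismatch between prediction and target")
  mean(abs(pred - target))
}

# Analytic gradient of mean |f(x) - t| for an all-1x1 network on an N x 3
# scaled pixel matrix. The L1 subgradient at 0 is taken as 0. Returns the
# loss and per-layer gradients.
net_loss_grad <- function(params, x, target) {
  nl <- params$n_layers
  acts <- vector("list", nl + 1L)  # acts[[l]] = input to layer l
  zs <- vector("list", nl)
  acts[[1]] <- x
  a <- x
  for (l in seq_len(nl)) {
    lay <- params$layers[[l]]
    z <- a %*% t(lay$w[, , 1, 1]) + rep(lay$b, each = nrow(a))
    zs[[l]] <- z
    a <- if (l < nl) pmax(z, 0) else z
    if (l < nl) acts[[l + 1]] <- a
  }
  diff <- a - target
  loss <- mean(abs(diff))
  dz <- sign(diff) / length(diff)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(w = crossprod(dz, acts[[l]]), b = colSums(dz))
    if (l > 1) {
      da <- dz %*% params$layers[[l]]$w[, , 1, 1]
      dz <- da * (zs[[l - 1]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

#' Train a network on a paired dataset by SGD
#'
#' Mini-batch stochastic gradient descent on the L1 loss in the network's
#' scaled space, with a cosine-annealed learning rate. One epoch is a full
#' pass over the shuffled training pairs; after every epoch the mean test
#' loss is evaluated, and the returned network carries the weights of the
#' epoch with the lowest test loss. Fully deterministic given the config
#' seed.
#'
#' @param params an all-1x1 [stainnet()] to initialize from.
#' @param data a [make_paired_dataset()] result with non-empty train and
#'   test splits.
#' @param config a [train_config()].
#' @return the trained \code{stainnet}; the \code{history} element records
#'   per-epoch train loss, test loss, learning rate and the selected epoch.
#' @export
train_stainnet <- function(params, data, config = train_config()) {
  stopifnot(inherits(params, "stainnet"), inherits(data, "paired_dataset"),
            inherits(config, "train_config"))
  if (!all(params$kernel_sizes == 1L))
    stop("training is implemented for all-1x1 networks")
  tr <- dataset_pairs(data, "train")
  te <- dataset_pairs(data, "test")
  if (length(tr) == 0 || length(te) == 0)
    stop("dataset must have non-empty train and test splits")
  as_xy <- function(p) list(x = scale_in(flatten_pixels(p$source)),
                            y = scale_in(flatten_pixels(p$target)))
  tr <- lapply(tr, as_xy)
  te <- lapply(te, as_xy)
  nl <- params$n_layers
  mom <- lapply(params$layers, function(l) list(w = 0 * l$w[, , 1, 1], b = 0 * l$b))
  hist_train <- hist_test <- hist_lr <- numeric(config$epochs)
  best_loss <- Inf; best_layers <- params$layers; best_epoch <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch - 1L, config)
      ord <- sample.int(length(tr))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      bl <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        if (is.null(config$pixel_subsample)) {
          x <- do.call(rbind, lapply(tr[idx], `[[`, "x"))
          y <- do.call(rbind, lapply(tr[idx], `[[`, "y"))
        } else {
          sel <- lapply(tr[idx], function(p)
            sample.int(nrow(p$x), min(config$pixel_subsample, nrow(p$x))))
          x <- do.call(rbind, Map(function(p, s) p$x[s, , drop = FALSE], tr[idx], sel))
          y <- do.call(rbind, Map(function(p, s) p$y[s, , drop = FALSE], tr[idx], sel))
        }
        lg <- net_loss_grad(params, x, y)
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        bl[bi] <- lg$loss
        for (l in seq_len(nl)) {
          gw <- lg$grads[[l]]$w + config$weight_decay * params$layers[[l]]$w[, , 1, 1]
          mom[[l]]$w <- config$momentum * mom[[l]]$w + gw
          mom[[l]]$b <- config$momentum * mom[[l]]$b + lg$grads[[l]]$b
          params$layers[[l]]$w[, , 1, 1] <- params$layers[[l]]$w[, , 1, 1] - lr * mom[[l]]$w
          params$layers[[l]]$b <- params$layers[[l]]$b - lr * mom[[l]]$b
        }
      }
      test_losses <- vapply(te, function(p)
        l1_loss(net_forward_pixels(params, p$x), p$y), 0)
      hist_train[epoch] <- mean(bl)
      hist_test[epoch] <- mean(test_losses)
      hist_lr[epoch] <- lr
      if (hist_test[epoch] < best_loss) {
        best_loss <- hist_test[epoch]
        best_layers <- params$layers
        best_epoch <- epoch
      }
    }
  })
  params$layers <- best_layers
  params$history <- list(train_loss = hist_train, test_loss = hist_test,
                         lr = hist_lr, selected = best_epoch)
  params
}

#' Distill a teacher normalizer into a pixel-wise network
#'
#' The central fitting function. The teacher — any image-to-image normalizer,
#' e.g. [oracle_teacher()], a closure around [reinhard_apply()], or an
#' externally trained model — is run over the source images to produce
#' ground-truth targets; the resulting paired dataset is split and the
#' student network is trained by [train_stainnet()]. Distillation converts a
#' mapping that may depend on whole-image content into a pure per-pixel
#' color map; for teachers that are themselves pixel-wise the student can
#' recover the map almost exactly, while content-dependent teachers are
#' approximated by their average color map (the train loss then plateaus
#' above zero).
#'
#' @param teacher a function taking and returning an RGB image array.
#' @param source_images list of at least 2 RGB images.
#' @param config a [train_config()].
#' @param n_layers,channels architecture of the student (default 3 x 32).
#' @param test_fraction held-out fraction for checkpoint selection.
#' @return a trained \code{stainnet} object.
#' @export
#' @examples
#' shift <- domain_shift()
#' imgs <- lapply(1:8, function(i)
#'   simulate_patch(scene_config(size = 32, seed = i))$image)
#' fit <- distill(oracle_teacher(shift), imgs,
#'                config = train_config(epochs = 3, seed = 1))
#' fit
distill <- function(teacher, source_images, config = train_config(),
                    n_layers = 3, channels = 32, test_fraction = 0.3) {
  stopifnot(is.function(teacher), is.list(source_images),
            length(source_images) >= 2)
  pairs <- vector("list", length(source_images))
  for (i in seq_along(source_images)) {
    tgt <- tryCatch(teacher(source_images[[i]]), error = function(e)
      stop("teacher failed on source image ", i, ": ", conditionMessage(e)))
    pairs[[i]] <- list(source = source_images[[i]], target = tgt)
  }
  n <- length(pairs)
  n_test <- max(1L, round(n * test_fraction))
  if (n - n_test < 1) stop("too few source images to populate both splits")
  split <- rep("train", n)
  perm <- with_seed(config$seed + 1L, sample.int(n))
  split[perm[seq_len(n_test)]] <- "test"
  ds <- structure(list(pairs = pairs, split = split, scene = NULL,
                       shift = NULL, seed = config$seed),
                  class = "paired_dataset")
  student <- stainnet(n_layers = n_layers, channels = channels,
                      seed = config$seed)
  train_stainnet(student, ds, config)
}
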