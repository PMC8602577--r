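#' Sparse non-negative matrix factorization of optical-density pixels
#'
#' Factorizes an N x 3 OD matrix as \code{OD ~ C \%*\% t(S)} with
#' nonnegative concentrations \code{C} (N x K), unit-norm nonnegative stain
#' columns in \code{S} (3 x K), minimizing
#' \deqn{||OD - C S^T||_F^2 + sparsity \cdot \sum |C|.}
#' Alternating minimization: the concentration step is an exact nonnegative
#' lasso coordinate descent (never increases the objective); the dictionary
#' step is a projected gradient step with backtracking, accepted only if the
#' combined objective does not increase, followed by unit-norm column
#' rescaling compensated in \code{C}. The objective sequence recorded per
#' outer iteration is therefore monotone non-increasing.
#'
#' @param od_pixels N x 3 matrix of optical densities (N >= 100).
#' @param k number of stains (default 2).
#' @param sparsity L1 penalty weight on concentrations (default 0.1).
#' @param iters maximum outer iterations (default 200).
#' @param seed seed for the random nonnegative initialization.
#' @param tol relative objective change declaring convergence (default
#'   1e-5, in line with common NMF solver tolerances; the objective decays
#'   as a slow power law long after the basis has stabilized).
#' @return list with \code{basis} (3 x K, hematoxylin-like first when K = 2),
#'   \code{conc} (N x K), \code{objective} (per-iteration values) and
#'   \code{converged} (logical; \code{FALSE} carries a warning).
#' @export
snmf <- function(od_pixels, k = 2, sparsity = 0.1, iters = 200, seed = 1,
                 tol = 1e-5) {
  stopifnot(is.matrix(od_pixels), ncol(od_pixels) == 3, k >= 1)
  if (nrow(od_pixels) < 100)
    stop("insufficient tissue: SNMF needs at least 100 OD pixels")
  d <- od_pixels
  s <- snmf_init(d, k, seed)
  cc <- matrix(0, nrow(d), k)
  obj <- function(cc, s) sum((d - cc %*% t(s))^2) + sparsity * sum(cc)
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(iters)) {
    # C-step: coordinate descent over stain columns, iterated to (near)
    # convergence so the dictionary step sees accurate concentrations
    for (pass in 1:25) {
      delta <- 0
      for (j in seq_len(k)) {
        r <- d - cc[, -j, drop = FALSE] %*% t(s[, -j, drop = FALSE])
        new_c <- pmax(0, (r %*% s[, j] - sparsity / 2) / sum(s[, j]^2))
        delta <- max(delta, max(abs(new_c - cc[, j])))
        cc[, j] <- new_c
      }
      if (delta < 1e-10) break
    }
    f_cur <- obj(cc, s)
    # S-step: projected gradient with backtracking on the full objective
    grad <- -2 * crossprod(d - cc %*% t(s), cc)  # 3 x K
    eta <- 1 / (2 * max(colSums(cc^2)) + 1e-12)
    for (try in 1:20) {
      s_new <- s - eta * grad
      s_new[s_new < 0] <- 0
      nrm <- sqrt(colSums(s_new^2))
      if (all(nrm > 1e-12)) {
        s_new <- sweep(s_new, 2, nrm, "/")
        cc_new <- sweep(cc, 2, nrm, "*")
        if (obj(cc_new, s_new) <= f_cur) {
          s <- s_new; cc <- cc_new; f_cur <- obj(cc, s)
          break
        }
      }
      eta <- eta / 2
    }
    objective <- c(objective, f_cur)
    if (it > 1 && abs(objective[it - 1] - f_cur) <=
          tol * max(1, objective[it - 1])) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("SNMF did not converge within ", iters,
            " iterations; returning best iterate")
  if (k == 2) {
    ord <- order_hematoxylin_first(s)
    if (!identical(unname(ord[, 1]), unname(s[, 1]))) cc <- cc[, 2:1, drop = FALSE]
    s <- ord
  }
  list(basis = s, conc = cc, objective = objective, converged = converged)
}

# Dictionary initialization. For k = 2 a deterministic warm start from the
# extreme angles of the leading SVD plane (the geometry Macenko exploits)
# puts the columns near the pure-stain directions, from which the
# alternating updates refine reliably; otherwise random nonnegative columns
# seeded by `seed`.
snmf_init <- function(d, k, seed) {
  d <- d[rowSums(d * d) > 1e-12, , drop = FALSE]  # blank pixels carry no angle
  if (k == 2 && nrow(d) >= 10) {
    sv <- svd(d, nu = 0, nv = min(3, ncol(d)))
    if (sv$d[2] > 1e-6 * sv$d[1]) {
      v <- sv$v[, 1:2]
      proj <- d %*% v
      for (j in 1:2) if (sum(proj[, j]) < 0) { v[, j] <- -v[, j]; proj[, j] <- -proj[, j] }
      phi <- atan2(proj[, 2], proj[, 1])
      lo <- stats::quantile(phi, 0.01, names = FALSE, type = 1)
      hi <- stats::quantile(phi, 0.99, names = FALSE, type = 1)
      s <- cbind(v %*% c(cos(lo), sin(lo)), v %*% c(cos(hi), sin(hi)))
      s[s < 0] <- 0
      nrm <- sqrt(colSums(s^2))
      if (all(nrm > 1e-9)) return(sweep(s, 2, nrm, "/"))
    }
  }
  s <- with_seed(seed, matrix(stats::runif(3 * k, 0.1, 1), 3, k))
  sweep(s, 2, sqrt(colSums(s^2)), "/")
}

#' Fit a Vahadane (SNMF) stain profile to a reference image
#'
#' As [macenko_fit()], but the stain basis comes from sparse non-negative
#' matrix factorization of the reference's tissue OD pixels.
#'
#' @inheritParams macenko_fit
#' @param sparsity,iters,seed passed to [snmf()].
#' @return an object of class \code{stain_profile}.
#' @export
vahadane_fit <- function(reference, beta = 0.15, sparsity = 0.1, iters = 200,
                         seed = 1) {
  check_rgb(reference)
  od <- sep_od_pixels(reference)
  tissue <- od[tissue_rows(od, beta), , drop = FALSE]
  if (nrow(tissue) < 100)
    stop("insufficient tissue: fewer than 100 pixels above the OD threshold")
  fit <- snmf(tissue, k = 2, sparsity = sparsity, iters = iters, seed = seed)
  conc <- stain_concentrations(od, fit$basis)
  max_conc <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  if (any(max_conc <= 0)) stop("degenerate reference: zero stain concentration")
  new_stain_profile(fit$basis, max_conc, "vahadane")
}

#' Normalize an image to a Vahadane stain profile
#'
#' The source basis is estimated by SNMF on the image's tissue pixels and its
#' columns are matched to the reference basis by minimal total angular
#' distance over the two possible pairings before concentration rescaling
#' and recomposition.
#'
#' @inheritParams macenko_apply
#' @param sparsity,iters,seed passed to [snmf()].
#' @return the normalized RGB image.
#' @export
vahadane_apply <- function(image, profile, beta = 0.15, sparsity = 0.1,
                           iters = 200, seed = 1) {
  check_rgb(image)
  stopifnot(inherits(profile, "stain_profile"))
  d <- dim(image)
  od <- sep_od_pixels(image)
  tissue <- od[tissue_rows(od, beta), , drop = FALSE]
  if (nrow(tissue) < 100)
    stop("insufficient tissue: fewer than 100 pixels above the OD threshold")
  fit <- snmf(tissue, k = 2, sparsity = sparsity, iters = iters, seed = seed)
  src <- fit$basis
  # match source columns to the reference basis by total angular distance
  keep <- angle_deg(src[, 1], profile$basis[, 1]) +
          angle_deg(src[, 2], profile$basis[, 2])
  swap <- angle_deg(src[, 2], profile$basis[, 1]) +
          angle_deg(src[, 1], profile$basis[, 2])
  if (swap < keep) src <- src[, 2:1]
  recompose_with_profile(image, src, profile, d)
}
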