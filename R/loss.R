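# ---------------------------------------------------------------------------
# Unsupervised objective: local normalized cross-correlation computed with
# separable box sums, the multi-resolution similarity loss, and a quadratic
# identity-deviation penalty on the geometric parameters.
# ---------------------------------------------------------------------------

# cumulative sum down the rows of a matrix, vectorized
cumsum_axis1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  v <- cumsum(as.vector(m))
  if (k > 1) {
    offs <- c(0, v[n * seq_len(k - 1)])
    matrix(v, n, k) - rep(offs, each = n)
  } else matrix(v, n, 1)
}

# windowed sum (radius r, zero extension) along the rows of a matrix
box1 <- function(m, r) {
  n <- nrow(m)
  cs <- rbind(0, cumsum_axis1(m))
  hi <- pmin(seq_len(n) + r, n) + 1L
  lo <- pmax(seq_len(n) - r, 1L)
  cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
}

# separable w^3 box sum over a 3D array (w odd); windows are clipped at the
# volume boundary (pair with a box sum of ones to count contributing voxels)
box_sum3 <- function(vol, w) {
  r <- (w - 1L) / 2L
  d <- dim(vol)
  a <- array(box1(matrix(vol, d[1]), r), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(box1(matrix(a, d[2]), r), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(box1(matrix(a, d[3]), r), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

# local NCC sufficient statistics shared by value and gradient
local_ncc_stats <- function(f, w_img, w, eps = 1e-5) {
  d <- dim(f)
  if (w == 0) {
    # global sentinel: single window covering the volume
    cnt <- length(f)
    mf <- mean(f); mw <- mean(w_img)
    cf <- f - mf; cw <- w_img - mw
    cross <- sum(cf * cw); varf <- sum(cf^2); varw <- sum(cw^2)
    den <- sqrt(varf * varw + eps)
    return(list(global = TRUE, mf = mf, mw = mw, cross = cross,
                varf = varf, varw = varw, den = den, ncc = cross / den))
  }
  ones <- array(1, d)
  cnt <- box_sum3(ones, w)
  sf <- box_sum3(f, w)
  sw <- box_sum3(w_img, w)
  sff <- box_sum3(f * f, w)
  sww <- box_sum3(w_img * w_img, w)
  sfw <- box_sum3(f * w_img, w)
  mf <- sf / cnt
  mw <- sw / cnt
  cross <- sfw - mf * sw
  varf <- sff - mf * sf
  varw <- sww - mw * sw
  den <- sqrt(pmax(varf * varw, 0) + eps)
  list(global = FALSE, mf = mf, mw = mw, cross = cross, varf = varf,
       varw = varw, den = den, ncc = cross / den)
}

#' Windowed local normalized cross-correlation
#'
#' Mean over all voxels of the local NCC computed in `w^3` neighbourhoods
#' (clipped at the boundary) via separable local sums:
#' \deqn{ncc = \sum (F-\bar F)(W-\bar W) /
#'   \sqrt{\sum(F-\bar F)^2 \sum(W-\bar W)^2 + \epsilon}.}
#' The `eps` guard makes flat windows contribute 0 rather than NaN. Values
#' lie in \eqn{[-1, 1]} up to `eps` effects. `w = 0` is a sentinel for a
#' single global window.
#'
#' @param f,w_img volumes of identical shape.
#' @param w odd window size (or 0 for global NCC).
#' @param eps variance guard, default `1e-5`.
#' @return scalar similarity in \eqn{[-1, 1]}.
#' @export
local_ncc <- function(f, w_img, w = 7, eps = 1e-5) {
  if (!all(dim(f) == dim(w_img))) stop("volume shapes differ")
  if (w != 0 && w %% 2 != 1) stop("window size must be odd (or 0 for global)")
  st <- local_ncc_stats(f, w_img, w, eps)
  if (st$global) st$ncc else mean(st$ncc)
}

# value and gradient in one pass (shared sufficient statistics)
local_ncc_value_grad <- function(f, w_img, w = 7, eps = 1e-5) {
  st <- local_ncc_stats(f, w_img, w, eps)
  if (st$global) {
    cf <- f - st$mf; cw <- w_img - st$mw
    return(list(value = st$ncc,
                grad = (cf - st$cross * st$varf * cw / st$den^2) / st$den))
  }
  a <- 1 / st$den
  b <- st$cross * st$varf / st$den^3
  nvox <- length(f)
  list(value = mean(st$ncc),
       grad = (f * box_sum3(a, w) - box_sum3(a * st$mf, w) -
                 w_img * box_sum3(b, w) + box_sum3(b * st$mw, w)) / nvox)
}

# d local_ncc / d w_img (same shape as the inputs)
local_ncc_grad <- function(f, w_img, w = 7, eps = 1e-5) {
  st <- local_ncc_stats(f, w_img, w, eps)
  if (st$global) {
    cf <- f - st$mf; cw <- w_img - st$mw
    return((cf - st$cross * st$varf * cw / st$den^2) / st$den)
  }
  a <- 1 / st$den
  b <- st$cross * st$varf / st$den^3
  nvox <- length(f)
  (f * box_sum3(a, w) - box_sum3(a * st$mf, w) -
      w_img * box_sum3(b, w) + box_sum3(b * st$mw, w)) / nvox
}

#' Multi-resolution similarity loss
#'
#' Weighted sum of negated local NCC values across pyramid levels,
#' \eqn{L_{sim} = \sum_{i=1}^{L} -2^{-(L-i)} NCC_w(F_i, W_i)}: the finest
#' level carries weight \eqn{-1}, the next \eqn{-1/2}, and so on. Lower is
#' better; identical pyramids at \eqn{L = 3} give \eqn{-1.75}.
#'
#' @param f_pyr,w_pyr lists of volumes, coarse to fine, equal lengths.
#' @param w NCC window size.
#' @return scalar loss.
#' @export
similarity_loss <- function(f_pyr, w_pyr, w = 7) {
  L <- length(f_pyr)
  if (length(w_pyr) != L) stop("pyramid lengths differ")
  s <- 0
  for (i in seq_len(L))
    s <- s - local_ncc(f_pyr[[i]], w_pyr[[i]], w) / 2^(L - i)
  s
}

#' Quadratic identity-deviation penalty on geometric parameters
#'
#' Sum of squared deviations from the identity transform, each component
#' normalized by its admissible half-range:
#' \eqn{\sum t^2 + \sum (r/\pi)^2 + \sum ((s-1)/0.5)^2 + \sum (h/\pi)^2}.
#' Zero iff the transform is the identity; strictly increasing in the
#' magnitude of every component.
#'
#' @param p `geometric_params`.
#' @return non-negative scalar.
#' @export
regularization <- function(p) {
  p <- unclass(p)
  sum(p[1:3]^2) + sum((p[4:6] / pi)^2) +
    sum(((p[7:9] - 1) / 0.5)^2) + sum((p[10:12] / pi)^2)
}

regularization_grad <- function(p) {
  p <- unclass(p)
  c(2 * p[1:3], 2 * p[4:6] / pi^2, 2 * (p[7:9] - 1) / 0.25,
    2 * p[10:12] / pi^2)
}

#' Total registration loss with breakdown
#'
#' Warps the moving image by `transform`, builds `levels`-deep pyramids of
#' the fixed and warped volumes, and returns
#' `total = sim + lambda * reg` with its components.
#'
#' @param fixed,moving volumes of identical shape.
#' @param transform `affine_transform` applied to `moving`.
#' @param params `geometric_params` entering the regularizer.
#' @param lambda regularization weight (default 0.01).
#' @param w NCC window size; `levels` pyramid depth.
#' @return list with fields `sim`, `reg`, `total`, `lambda`.
#' @export
total_loss <- function(fixed, moving, transform, params, lambda = 0.01,
                       w = 7, levels = 3) {
  warped <- warp_volume(moving, transform)
  f_pyr <- build_pyramid(fixed, levels)
  w_pyr <- build_pyramid(warped, levels)
  sim <- similarity_loss(f_pyr, w_pyr, w)
  reg <- regularization(params)
  list(sim = sim, reg = reg, total = sim + lambda * reg, lambda = lambda)
}

# Gradient of the similarity part of total_loss with respect to the warped
# full-resolution moving image.
similarity_loss_grad_warped <- function(fixed, warped, w = 7, levels = 3) {
  f_pyr <- build_pyramid(fixed, levels)
  w_pyr <- build_pyramid(warped, levels)
  g <- array(0, dim = dim(warped))
  for (i in seq_len(levels)) {
    gi <- -local_ncc_grad(f_pyr[[i]], w_pyr[[i]], w) / 2^(levels - i)
    g <- g + if (all(dim(w_pyr[[i]]) == dim(warped))) gi else
      resize_adjoint(gi, dim(warped))
  }
  g
}
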