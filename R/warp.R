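# ---------------------------------------------------------------------------
# Spatial-transformer warping: affine sampling grids and trilinear / nearest
# resampling, plus the adjoint and Jacobian pieces the training loop needs.
# Volumes are plain 3D arrays indexed [x, y, z] (first array axis fastest).
# ---------------------------------------------------------------------------

# Normalized coordinates of every voxel centre of `shape`, as a 3 x N matrix
# in array (column-major) order. Axis of length n maps voxel i (0-based) to
# 2 i / (n - 1) - 1.
norm_mesh <- function(shape) {
  stopifnot(length(shape) == 3, all(shape >= 2))
  ax <- lapply(shape, function(n) 2 * (seq_len(n) - 1) / (n - 1) - 1)
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  rbind(rep(ax[[1]], times = n2 * n3),
        rep(rep(ax[[2]], each = n1), times = n3),
        rep(ax[[3]], each = n1 * n2))
}

norm_to_voxel <- function(coords, shape) {
  (coords + 1) * (shape - 1) / 2
}

#' Affine sampling grid
#'
#' For every voxel centre `x` of the target shape (normalized coordinates),
#' stores `A x` — the location to *sample from* in the moving image
#' (pull/backward-warping convention).
#'
#' @param a `affine_transform` in the normalized convention.
#' @param shape target grid shape (3 positive integers).
#' @return object of class `sampling_grid` with fields `coords` (3 x N
#'   matrix of normalized source coordinates in array order) and `shape`.
#' @export
affine_grid <- function(a, shape) {
  stopifnot(inherits(a, "affine_transform"), length(shape) == 3)
  if (any(shape < 1)) stop("target shape must be positive on every axis")
  x <- norm_mesh(shape)
  coords <- a$mat[1:3, 1:3] %*% x + a$mat[1:3, 4]
  structure(list(coords = coords, shape = as.integer(shape)),
            class = "sampling_grid")
}

# Trilinear interpolation of `vol` at 0-based voxel coordinates (3 x N).
# Out-of-bounds corners contribute zero (the volume is embedded in a zero
# border so no per-corner bounds checks are needed). Returns values; with
# grad = TRUE also the derivative w.r.t. each voxel coordinate (3 x N).
trilinear_sample <- function(vol, vox, grad = FALSE) {
  d <- dim(vol)
  dp <- d + 3L                              # 1 low + 2 high zero border
  vp <- array(0, dp)
  vp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  v <- as.vector(vp)
  x <- pmin(pmax(vox[1, ], -1), d[1])
  y <- pmin(pmax(vox[2, ], -1), d[2])
  z <- pmin(pmax(vox[3, ], -1), d[3])
  ix <- floor(x); iy <- floor(y); iz <- floor(z)
  fx <- x - ix; fy <- y - iy; fz <- z - iz
  base <- (ix + 2) + dp[1] * ((iy + 1) + dp[2] * (iz + 1))
  o10 <- 1; o01 <- dp[1]; o001 <- dp[1] * dp[2]
  v000 <- v[base]
  v100 <- v[base + o10]
  v010 <- v[base + o01]
  v110 <- v[base + o10 + o01]
  v001 <- v[base + o001]
  v101 <- v[base + o10 + o001]
  v011 <- v[base + o01 + o001]
  v111 <- v[base + o10 + o01 + o001]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  c00 <- v000 * gx + v100 * fx
  c10 <- v010 * gx + v110 * fx
  c01 <- v001 * gx + v101 * fx
  c11 <- v011 * gx + v111 * fx
  c0 <- c00 * gy + c10 * fy
  c1 <- c01 * gy + c11 * fy
  val <- c0 * gz + c1 * fz
  if (!grad) return(val)
  # derivative along each axis: interpolate forward differences
  dxc0 <- (v100 - v000) * gy + (v110 - v010) * fy
  dxc1 <- (v101 - v001) * gy + (v111 - v011) * fy
  dvx <- dxc0 * gz + dxc1 * fz
  dyc0 <- c10 - c00
  dyc1 <- c11 - c01
  dvy <- dyc0 * gz + dyc1 * fz
  dvz <- c1 - c0
  list(value = val, grad = rbind(dvx, dvy, dvz))
}

# Adjoint of trilinear_sample: scatter `values` back onto a grid of `shape`
# with the same corner weights. Used to backpropagate through downsampling.
trilinear_scatter <- function(shape, vox, values) {
  dp <- shape + 3L
  np <- prod(dp)
  x <- pmin(pmax(vox[1, ], -1), shape[1])
  y <- pmin(pmax(vox[2, ], -1), shape[2])
  z <- pmin(pmax(vox[3, ], -1), shape[3])
  ix <- floor(x); iy <- floor(y); iz <- floor(z)
  fx <- x - ix; fy <- y - iy; fz <- z - iz
  base <- (ix + 2) + dp[1] * ((iy + 1) + dp[2] * (iz + 1))
  o10 <- 1; o01 <- dp[1]; o001 <- dp[1] * dp[2]
  idx <- c(base, base + o10, base + o01, base + o10 + o01,
           base + o001, base + o10 + o001, base + o01 + o001,
           base + o10 + o01 + o001)
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  w <- c(gx * gy * gz, fx * gy * gz, gx * fy * gz, fx * fy * gz,
         gx * gy * fz, fx * gy * fz, gx * fy * fz, fx * fy * fz) *
    rep(values, 8L)
  acc <- as.vector(Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                        x = w, dims = c(np, 1)))
  array(acc, dp)[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)]
}

#' Warp a 3D volume by an affine transform
#'
#' Resamples `vol` at the [affine_grid()] locations. Intensity images use
#' trilinear interpolation; label maps should use nearest-neighbour.
#' Out-of-bounds samples are filled with zero.
#'
#' @param vol 3D array (finite values).
#' @param a `affine_transform` (normalized convention, sampling direction).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param shape output shape; defaults to `dim(vol)`.
#' @return warped 3D array of dimension `shape`.
#' @export
warp_volume <- function(vol, a, interpolation = c("trilinear", "nearest"),
                        shape = dim(vol)) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(dim(vol)) == 3, all(is.finite(vol)))
  g <- affine_grid(a, shape)
  vox <- norm_to_voxel(g$coords, dim(vol))
  if (interpolation == "trilinear") {
    array(trilinear_sample(vol, vox), dim = shape)
  } else {
    d <- dim(vol)
    ir <- round(vox)
    ok <- ir[1, ] >= 0 & ir[1, ] <= d[1] - 1 &
      ir[2, ] >= 0 & ir[2, ] <= d[2] - 1 &
      ir[3, ] >= 0 & ir[3, ] <= d[3] - 1
    lin <- 1 + pmin(pmax(ir[1, ], 0), d[1] - 1) +
      d[1] * (pmin(pmax(ir[2, ], 0), d[2] - 1) +
                d[2] * pmin(pmax(ir[3, ], 0), d[3] - 1))
    array(as.vector(vol)[lin] * ok, dim = shape)
  }
}

#' Warp every frame of a 4D series by one affine transform
#'
#' The single matrix estimated from the temporal-mean image is applied
#' independently to each time frame; the frame count is preserved.
#'
#' @param series 4D array (x, y, z, t) with at least one frame.
#' @param a `affine_transform`.
#' @param interpolation passed to [warp_volume()].
#' @return warped 4D array.
#' @export
warp_timeseries <- function(series, a,
                            interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(series)
  if (length(d) != 4 || d[4] < 1) stop("series must be 4D with >= 1 frame")
  out <- array(0, dim = d)
  for (tt in seq_len(d[4]))
    out[, , , tt] <- warp_volume(series[, , , tt], a, interpolation)
  out
}

#' Trilinear resize of a volume (corner-aligned)
#'
#' @param vol 3D array; `shape` target dimensions.
#' @param shape integer triple.
#' @return resized array.
#' @export
resize_volume <- function(vol, shape) {
  stopifnot(length(shape) == 3, all(shape >= 2))
  if (all(dim(vol) == shape)) return(vol)
  coords <- norm_mesh(shape)
  vox <- norm_to_voxel(coords, dim(vol))
  array(trilinear_sample(vol, vox), dim = shape)
}

# Adjoint of resize_volume: push a gradient on the resized grid back to the
# source grid.
resize_adjoint <- function(grad_out, in_shape) {
  out_shape <- dim(grad_out)
  coords <- norm_mesh(out_shape)
  vox <- norm_to_voxel(coords, in_shape)
  trilinear_scatter(in_shape, vox, as.vector(grad_out))
}

# Gradient of sum(grad_out * warp_volume(vol, A)) with respect to the top
# three rows of A (3 x 4 matrix). `grad_out` has the target shape.
warp_affine_grad <- function(vol, a, grad_out) {
  shape <- dim(grad_out)
  x <- norm_mesh(shape)
  coords <- a$mat[1:3, 1:3] %*% x + a$mat[1:3, 4]
  d <- dim(vol)
  vox <- norm_to_voxel(coords, d)
  sg <- trilinear_sample(vol, vox, grad = TRUE)
  # chain: d value / d normalized coord = d value / d voxel * (n-1)/2
  gc <- sg$grad * ((d - 1) / 2)          # 3 x N, recycled by row
  g <- as.vector(grad_out)
  xh <- rbind(x, 1)
  (gc * rep(g, each = 3)) %*% t(xh)      # 3 x 4
}
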