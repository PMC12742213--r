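# ---------------------------------------------------------------------------
# Geometric transformation model
#
# All affine matrices in this package act in a normalized coordinate frame:
# the voxel-centre lattice of each axis is mapped linearly onto [-1, 1]
# (voxel 0 -> -1, voxel n-1 -> +1), so the origin sits at the geometric
# centre of the volume and parameters are resolution independent. Matrices
# are *sampling* (pull) maps: warping a moving image M by transform A
# produces an output whose value at target coordinate x is M(A x). The
# forward motion of image content corresponds to the inverse matrix.
# ---------------------------------------------------------------------------

PARAM_NAMES <- c("tx", "ty", "tz", "rx", "ry", "rz",
                 "sx", "sy", "sz", "hxy", "hxz", "hyz")

#' Construct a geometric parameter vector
#'
#' Bundles the 12 scalars of the affine model: translation `t` (fraction of
#' the half-extent per axis, in \eqn{[-0.5, 0.5]}), rotation `r` (radians, in
#' \eqn{[-\pi, \pi]}), scaling `s` (dimensionless, in \eqn{[0.5, 1.5]}) and
#' shear `h` (dimensionless, in \eqn{[-\pi, \pi]}).
#'
#' @param t,r,s,h numeric triples (see ranges above).
#' @return a named numeric vector of class `geometric_params`.
#' @export
geometric_params <- function(t = c(0, 0, 0), r = c(0, 0, 0),
                             s = c(1, 1, 1), h = c(0, 0, 0)) {
  stopifnot(length(t) == 3, length(r) == 3, length(s) == 3, length(h) == 3)
  p <- c(t, r, s, h)
  names(p) <- PARAM_NAMES
  if (any(abs(t) > 0.5 + 1e-12))
    stop("translation components must lie in [-0.5, 0.5]")
  if (any(abs(r) > pi + 1e-12) || any(abs(h) > pi + 1e-12))
    stop("rotation and shear components must lie in [-pi, pi]")
  if (any(s < 0.5 - 1e-12) || any(s > 1.5 + 1e-12))
    stop("scaling components must lie in [0.5, 1.5]")
  class(p) <- "geometric_params"
  p
}

#' @export
print.geometric_params <- function(x, ...) {
  cat("geometric parameters (t, r, s, h):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

param_t <- function(p) unclass(p)[1:3]
param_r <- function(p) unclass(p)[4:6]
param_s <- function(p) unclass(p)[7:9]
param_h <- function(p) unclass(p)[10:12]

#' Construct an affine transform object
#'
#' @param mat 4x4 homogeneous matrix with bottom row (0,0,0,1).
#' @param convention coordinate-frame tag; only `"normalized"` is used
#'   internally (see package conventions).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(mat, convention = "normalized") {
  mat <- as.matrix(mat)
  stopifnot(all(dim(mat) == c(4, 4)))
  if (max(abs(mat[4, ] - c(0, 0, 0, 1))) > 1e-10)
    stop("bottom row of an affine matrix must be (0, 0, 0, 1)")
  structure(list(mat = unname(mat), convention = convention),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine transform (", x$convention, " frame, sampling convention):\n",
      sep = "")
  print(round(x$mat, 6))
  invisible(x)
}

#' The identity transform
#' @export
identity_transform <- function() affine_transform(diag(4))

#' Translation matrix
#'
#' Identity matrix with last column `(t_x, t_y, t_z, 1)`; `t` is expressed in
#' the normalized frame.
#'
#' @param t numeric translation triple.
#' @return `affine_transform`.
#' @export
translation_matrix <- function(t) {
  stopifnot(length(t) == 3, all(is.finite(t)))
  m <- diag(4)
  m[1:3, 4] <- t
  affine_transform(m)
}

#' Rotation matrix
#'
#' Ordered product of the three axis rotations, `R = R_x R_y R_z`. The 3x3
#' linear block is orthonormal with determinant +1.
#'
#' @param r rotation triple in radians; each component must lie in
#'   \eqn{[-\pi, \pi]} (out-of-range values are rejected, not wrapped).
#' @return `affine_transform`.
#' @export
rotation_matrix <- function(r) {
  stopifnot(length(r) == 3)
  if (any(abs(r) > pi + 1e-12))
    stop("rotation components must lie in [-pi, pi]")
  rx <- diag(4); ry <- diag(4); rz <- diag(4)
  c1 <- cos(r[1]); s1 <- sin(r[1])
  c2 <- cos(r[2]); s2 <- sin(r[2])
  c3 <- cos(r[3]); s3 <- sin(r[3])
  rx[2:3, 2:3] <- matrix(c(c1, s1, -s1, c1), 2)
  ry[c(1, 3), c(1, 3)] <- matrix(c(c2, -s2, s2, c2), 2)
  rz[1:2, 1:2] <- matrix(c(c3, s3, -s3, c3), 2)
  affine_transform(rx %*% ry %*% rz)
}

#' Scaling matrix
#' @param s scaling triple, each component in \eqn{[0.5, 1.5]}.
#' @return `affine_transform` with diagonal `(s_x, s_y, s_z, 1)`.
#' @export
scaling_matrix <- function(s) {
  stopifnot(length(s) == 3)
  if (any(s < 0.5 - 1e-12) || any(s > 1.5 + 1e-12))
    stop("scaling components must lie in [0.5, 1.5]")
  affine_transform(diag(c(s, 1)))
}

#' Shearing matrix
#'
#' Upper-triangular unit-diagonal shear with entries `h_xy`, `h_xz`, `h_yz`.
#' @param h shear triple, each component in \eqn{[-\pi, \pi]}.
#' @return `affine_transform`.
#' @export
shearing_matrix <- function(h) {
  stopifnot(length(h) == 3)
  if (any(abs(h) > pi + 1e-12))
    stop("shear components must lie in [-pi, pi]")
  m <- diag(4)
  m[1, 2] <- h[1]; m[1, 3] <- h[2]; m[2, 3] <- h[3]
  affine_transform(m)
}

#' Compose the full affine matrix from geometric parameters
#'
#' Ordered product `A = T R S H`, with the rotation, scaling and shear
#' factors conjugated so that they act about `center` (translate the pivot
#' to the origin, apply, translate back). Translation is applied in the
#' normalized frame.
#'
#' @param p `geometric_params` (or a plain in-range 12-vector).
#' @param center pivot point in normalized coordinates (default: origin,
#'   the volume centre). Use [normalize_coord()] to convert a voxel-space
#'   centre of mass.
#' @return `affine_transform`.
#' @export
compose_affine <- function(p, center = c(0, 0, 0)) {
  if (!inherits(p, "geometric_params"))
    p <- geometric_params(p[1:3], p[4:6], p[7:9], p[10:12])
  stopifnot(length(center) == 3)
  Tm <- translation_matrix(param_t(p))$mat
  R <- rotation_matrix(param_r(p))$mat
  S <- scaling_matrix(param_s(p))$mat
  H <- shearing_matrix(param_h(p))$mat
  Cm <- diag(4); Cm[1:3, 4] <- center
  Ci <- diag(4); Ci[1:3, 4] <- -center
  affine_transform(Tm %*% Cm %*% R %*% S %*% H %*% Ci)
}

# Partial derivatives dA/dtheta_k for the 12 parameters: product rule with
# one elementary factor differentiated. Used by the training backward pass.
compose_affine_jacobian <- function(p, center = c(0, 0, 0)) {
  p <- unclass(p)
  t <- p[1:3]; r <- p[4:6]; s <- p[7:9]; h <- p[10:12]
  c1 <- cos(r[1]); s1 <- sin(r[1])
  c2 <- cos(r[2]); s2 <- sin(r[2])
  c3 <- cos(r[3]); s3 <- sin(r[3])
  rx <- diag(4); ry <- diag(4); rz <- diag(4)
  rx[2:3, 2:3] <- matrix(c(c1, s1, -s1, c1), 2)
  ry[c(1, 3), c(1, 3)] <- matrix(c(c2, -s2, s2, c2), 2)
  rz[1:2, 1:2] <- matrix(c(c3, s3, -s3, c3), 2)
  drx <- matrix(0, 4, 4); drx[2:3, 2:3] <- matrix(c(-s1, c1, -c1, -s1), 2)
  dry <- matrix(0, 4, 4); dry[c(1, 3), c(1, 3)] <- matrix(c(-s2, -c2, c2, -s2), 2)
  drz <- matrix(0, 4, 4); drz[1:2, 1:2] <- matrix(c(-s3, c3, -c3, -s3), 2)
  Tm <- diag(4); Tm[1:3, 4] <- t
  R <- rx %*% ry %*% rz
  S <- diag(c(s, 1))
  H <- diag(4); H[1, 2] <- h[1]; H[1, 3] <- h[2]; H[2, 3] <- h[3]
  Cm <- diag(4); Cm[1:3, 4] <- center
  Ci <- diag(4); Ci[1:3, 4] <- -center
  jac <- vector("list", 12)
  RSHC <- R %*% S %*% H %*% Ci
  TC <- Tm %*% Cm
  for (k in 1:3) {                      # translations
    dT <- matrix(0, 4, 4); dT[k, 4] <- 1
    jac[[k]] <- dT %*% Cm %*% RSHC
  }
  dR <- list(drx %*% ry %*% rz, rx %*% dry %*% rz, rx %*% ry %*% drz)
  for (k in 1:3)                        # rotations
    jac[[3 + k]] <- TC %*% dR[[k]] %*% S %*% H %*% Ci
  for (k in 1:3) {                      # scalings
    dS <- matrix(0, 4, 4); dS[k, k] <- 1
    jac[[6 + k]] <- TC %*% R %*% dS %*% H %*% Ci
  }
  hpos <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {                      # shears
    dH <- matrix(0, 4, 4); dH[hpos[[k]][1], hpos[[k]][2]] <- 1
    jac[[6 + 3 + k]] <- TC %*% R %*% S %*% dH %*% Ci
  }
  jac
}

#' Squash 12 unconstrained scalars into the admissible parameter ranges
#'
#' Smooth, differentiable bounded mapping (the network head emits
#' unconstrained reals): `t = 0.5 tanh(raw)`, `r = pi tanh(raw)`,
#' `s = 1 + 0.5 tanh(raw)`, `h = pi tanh(raw)`. Zero input maps to the
#' identity transform.
#'
#' @param raw numeric vector of 12 unconstrained scalars ordered
#'   (t, r, s, h).
#' @return `geometric_params`.
#' @export
constrain_params <- function(raw) {
  stopifnot(length(raw) == 12, all(is.finite(raw)))
  th <- tanh(raw)
  geometric_params(t = 0.5 * th[1:3], r = pi * th[4:6],
                   s = 1 + 0.5 * th[7:9], h = pi * th[10:12])
}

# d(constrained)/d(raw), elementwise.
constrain_params_grad <- function(raw) {
  d <- 1 - tanh(raw)^2
  d * c(rep(0.5, 3), rep(pi, 3), rep(0.5, 3), rep(pi, 3))
}

#' Centre of mass of a non-negative volume
#'
#' Intensity-weighted mean voxel position
#' \eqn{c = \sum_p p I(p) / \sum_p I(p)}, in 0-based voxel coordinates.
#'
#' @param vol non-negative 3D array, not all zero.
#' @return numeric triple in voxel units.
#' @export
center_of_mass <- function(vol) {
  stopifnot(length(dim(vol)) == 3)
  if (any(vol < 0)) stop("center_of_mass requires a non-negative image")
  tot <- sum(vol)
  if (tot == 0) stop("degenerate image: total intensity is zero")
  d <- dim(vol)
  mx <- apply(vol, 1, sum)
  my <- apply(vol, 2, sum)
  mz <- apply(vol, 3, sum)
  c(sum((seq_len(d[1]) - 1) * mx),
    sum((seq_len(d[2]) - 1) * my),
    sum((seq_len(d[3]) - 1) * mz)) / tot
}

#' Convert a voxel coordinate to the normalized frame
#'
#' Voxel centre `i` (0-based) on an axis of length `n` maps to
#' `2 i / (n - 1) - 1`.
#'
#' @param v voxel-space coordinate triple.
#' @param shape volume dimensions.
#' @export
normalize_coord <- function(v, shape) {
  stopifnot(length(v) == 3, length(shape) == 3)
  2 * v / (shape - 1) - 1
}

#' Centre-of-mass pre-alignment
#'
#' Pure translation moving the centre of mass of `moving` onto that of
#' `fixed`; used as the initialization folded into the accumulated
#' transform of the registration cascade. In the sampling convention the
#' returned matrix carries the offset `COM(moving) - COM(fixed)`
#' (normalized units); the forward motion of the image content is the
#' opposite displacement.
#'
#' @param fixed,moving non-negative 3D arrays of identical shape.
#' @return `affine_transform`.
#' @export
com_align <- function(fixed, moving) {
  stopifnot(all(dim(fixed) == dim(moving)))
  cf <- normalize_coord(center_of_mass(fixed), dim(fixed))
  cm <- normalize_coord(center_of_mass(moving), dim(moving))
  translation_matrix(cm - cf)
}

#' Accumulate a cascade of stage transforms into one matrix
#'
#' Given transforms in application order (first applied first), returns the
#' single matrix whose one-shot warp equals warping sequentially by each
#' stage — the defined semantics of the cascade (the original moving image
#' is resampled exactly once by the accumulated matrix). In the sampling
#' convention this is the left-to-right matrix product
#' `A_1 %*% A_2 %*% ... %*% A_n`; expressed as forward maps it is the
#' ordered product with the first-applied stage rightmost.
#'
#' @param transforms non-empty list of `affine_transform`s sharing one
#'   convention, in application order.
#' @return `affine_transform`.
#' @export
accumulate_transforms <- function(transforms) {
  if (length(transforms) == 0) stop("empty transform list")
  conv <- unique(vapply(transforms, function(a) a$convention, ""))
  if (length(conv) != 1) stop("transforms use mixed coordinate conventions")
  affine_transform(Reduce(`%*%`, lapply(transforms, function(a) a$mat)),
                   convention = conv)
}

#' Invert an affine transform
#' @param a `affine_transform`.
#' @export
invert_transform <- function(a) {
  affine_transform(solve(a$mat), convention = a$convention)
}

# --- serialization ---------------------------------------------------------

#' Write / read an affine matrix as 4 lines of plain text
#'
#' @param a `affine_transform`; `path` output file. A JSON sidecar with the
#'   12-parameter record can be written alongside via `params`.
#' @param path file path for the 4-line matrix.
#' @param params optional `geometric_params` stored in `<path>.json`
#'   together with the convention tag.
#' @export
write_affine <- function(a, path, params = NULL) {
  mat <- a$mat
  writeLines(apply(mat, 1, function(r) paste(sprintf("%.10g", r),
                                             collapse = " ")), path)
  side <- list(convention = a$convention)
  if (!is.null(params)) side$params <- as.list(unclass(params))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Convert a normalized-frame transform to voxel or world space
#'
#' The internal matrices act on normalized coordinates
#' `x = 2 v / (n - 1) - 1` (voxel index `v`, axis length `n`). With the
#' homogeneous map `N: v -> x` this conversion is `N^-1 A N` for 0-based
#' voxel coordinates, additionally conjugated by `diag(spacing)` for
#' axis-aligned world coordinates. Written alongside the normalized matrix
#' by the `register` command for interoperability.
#'
#' @param a `affine_transform` in the normalized convention.
#' @param shape volume dimensions the transform refers to.
#' @param spacing voxel spacing (world conversion only).
#' @param to `"voxel"` or `"world"`.
#' @return `affine_transform` tagged with the new convention.
#' @export
convert_affine <- function(a, shape, spacing = c(1, 1, 1),
                           to = c("voxel", "world")) {
  to <- match.arg(to)
  stopifnot(a$convention == "normalized", length(shape) == 3)
  Nm <- diag(c(2 / (shape - 1), 1))
  Nm[1:3, 4] <- -1
  m <- solve(Nm) %*% a$mat %*% Nm
  if (to == "world") {
    S <- diag(c(spacing, 1))
    m <- S %*% m %*% solve(S)
  }
  affine_transform(m, convention = to)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  rows <- lapply(readLines(path), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, rows)
  conv <- "normalized"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (!is.null(side$convention)) conv <- side$convention
  }
  affine_transform(mat, convention = conv)
}
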