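# ---------------------------------------------------------------------------
# Synthetic phantom cohorts: brain-like intensity volumes with nested
# labelled structures, seeded affine misalignments and additive noise.
# These stand in for an in-house animal cohort and atlas, which are not
# publicly deposited; they make training, parameter-recovery and metric
# tests reproducible with no external data.
# ---------------------------------------------------------------------------

# smooth 3D box blur (3^3 kernel), used to soften structure edges
box_blur3 <- function(vol, passes = 1L) {
  for (i in seq_len(passes)) {
    s <- box_sum3(vol, 3L)
    n <- box_sum3(array(1, dim(vol)), 3L)
    vol <- s / n
  }
  vol
}

#' Generate a brain-like labelled phantom
#'
#' Deterministic per seed: an ellipsoidal "brain" containing `K` interior
#' structures (off-centre ellipsoids of distinct intensity arranged
#' asymmetrically so rotations are identifiable), a smooth dome-shaped
#' intensity profile, per-subject random jitter of structure positions and
#' sizes, light smoothing, and min-max normalization to `[0, 1]`.
#'
#' @param seed integer; same seed gives voxel-identical phantoms.
#' @param shape volume dimensions (each >= 32).
#' @param K number of labelled structures including the brain shell
#'   (2 to 7).
#' @return list of class `phantom` with `intensity` (3D array in `[0, 1]`),
#'   `labels` (integer array, 0 background, 1 brain, 2..K interior),
#'   `seed`, `shape`.
#' @export
generate_phantom <- function(seed = 1L, shape = c(64L, 64L, 32L), K = 5L) {
  if (any(shape < 32)) stop("phantom shape must be at least 32 per axis")
  if (K < 2) stop("K must be at least 2")
  if (K > 7) stop("K too large to place interior structures without overlap")
  set.seed(seed)
  d <- as.integer(shape)
  mesh <- norm_mesh(d)                        # 3 x N normalized coords
  x <- mesh[1, ]; y <- mesh[2, ]; z <- mesh[3, ]

  jit <- function(sd) stats::rnorm(1, 0, sd)
  # brain envelope: slightly jittered ellipsoid
  br <- c(0.72, 0.80, 0.70) * (1 + stats::rnorm(3, 0, 0.03))
  bc <- c(jit(0.02), jit(0.02), jit(0.02))
  rho2 <- ((x - bc[1]) / br[1])^2 + ((y - bc[2]) / br[2])^2 +
    ((z - bc[3]) / br[3])^2
  brain <- rho2 <= 1

  # canonical asymmetric layout of interior structures (normalized frame)
  base_centres <- list(c(0.30, 0.28, 0.10), c(-0.32, 0.05, -0.12),
                       c(0.05, -0.38, 0.18), c(-0.12, 0.33, -0.25),
                       c(0.25, -0.15, -0.28), c(-0.30, -0.30, 0.22))
  base_radii <- list(c(0.22, 0.16, 0.20), c(0.16, 0.20, 0.14),
                     c(0.14, 0.13, 0.16), c(0.12, 0.14, 0.11),
                     c(0.11, 0.12, 0.13), c(0.10, 0.11, 0.10))
  labels <- array(0L, d)
  labels[brain] <- 1L
  vol <- array(0, d)
  vol[brain] <- 0.35 + 0.30 * (1 - rho2[brain])   # dome profile
  n_inner <- K - 1L
  vals <- seq(0.95, 0.55, length.out = max(n_inner, 1))
  for (k in seq_len(n_inner)) {
    cc <- base_centres[[k]] * (1 + stats::rnorm(3, 0, 0.06)) +
      stats::rnorm(3, 0, 0.02)
    rr <- base_radii[[k]] * (1 + stats::rnorm(3, 0, 0.08))
    e2 <- ((x - cc[1]) / rr[1])^2 + ((y - cc[2]) / rr[2])^2 +
      ((z - cc[3]) / rr[3])^2
    inside <- e2 <= 1 & brain
    if (!any(inside)) stop("failed to place an interior structure")
    labels[inside] <- k + 1L
    vol[inside] <- vals[k] * (1 - 0.3 * e2[inside])
  }
  # smooth low-frequency intensity gradient + edge softening
  grad <- 0.04 * (stats::rnorm(1) * x + stats::rnorm(1) * y +
                    stats::rnorm(1) * z)
  vol <- array(vol + grad * (labels > 0), d)
  vol <- box_blur3(vol, passes = 2L)
  vol <- (vol - min(vol)) / (max(vol) - min(vol))
  structure(list(intensity = vol, labels = labels, seed = as.integer(seed),
                 shape = d), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %s, %d structures, seed %d\n",
              paste(x$shape, collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0L)), x$seed))
  invisible(x)
}

#' Default misalignment sampling ranges
#'
#' Milder than the hard constraint bounds of the transformation model so
#' that recovery experiments are well-posed; the full constraint ranges can
#' be requested with `full = TRUE`.
#'
#' @param full sample across the entire admissible parameter space.
#' @export
default_param_ranges <- function(full = FALSE) {
  if (full)
    list(trans = 0.5, rot = pi, scale = c(0.5, 1.5), shear = pi)
  else
    list(trans = 0.15, rot = 0.3, scale = c(0.9, 1.1), shear = 0.1)
}

#' Sample misalignment parameters uniformly within ranges
#'
#' @param seed integer seed (deterministic draws).
#' @param ranges list with `trans`, `rot`, `scale`, `shear`; must lie
#'   within the model's constraint intervals.
#' @return `geometric_params`.
#' @export
sample_affine_params <- function(seed = 1L, ranges = default_param_ranges()) {
  if (ranges$trans > 0.5 + 1e-12 || ranges$rot > pi + 1e-12 ||
      ranges$shear > pi + 1e-12 || ranges$scale[1] < 0.5 - 1e-12 ||
      ranges$scale[2] > 1.5 + 1e-12)
    stop("sampling ranges exceed the constraint intervals")
  set.seed(seed)
  geometric_params(
    t = stats::runif(3, -ranges$trans, ranges$trans),
    r = stats::runif(3, -ranges$rot, ranges$rot),
    s = stats::runif(3, ranges$scale[1], ranges$scale[2]),
    h = stats::runif(3, -ranges$shear, ranges$shear))
}

#' Build a misaligned (fixed, moving) pair from a phantom
#'
#' The fixed image is the phantom itself; the moving image is the phantom
#' warped by the *inverse* of the ground-truth transform (plus optional
#' Gaussian noise), labels warped nearest-neighbour. Registering moving to
#' fixed should therefore recover exactly the ground-truth transform.
#'
#' @param phantom from [generate_phantom()].
#' @param params `geometric_params` of the ground-truth misalignment.
#' @param noise_sd Gaussian noise standard deviation relative to the unit
#'   intensity range (default 0).
#' @param noise_seed seed for the noise draw.
#' @return list with `fixed`, `fixed_labels`, `moving`, `moving_labels`,
#'   `gt_transform` (`affine_transform`), `gt_params`, `center`.
#' @export
make_pair <- function(phantom, params, noise_sd = 0, noise_seed = 1L) {
  ctr <- normalize_coord(center_of_mass(phantom$intensity), phantom$shape)
  a_gt <- compose_affine(params, center = ctr)
  a_inv <- invert_transform(a_gt)
  moving <- warp_volume(phantom$intensity, a_inv)
  moving_labels <- warp_volume(phantom$labels, a_inv, "nearest")
  if (noise_sd > 0) {
    set.seed(noise_seed)
    moving <- moving + array(stats::rnorm(length(moving), 0, noise_sd),
                             dim(moving))
  }
  list(fixed = phantom$intensity, fixed_labels = phantom$labels,
       moving = moving, moving_labels = moving_labels,
       gt_transform = a_gt, gt_params = params, center = ctr)
}

#' Generate a seeded cohort of misaligned phantom pairs
#'
#' One phantom (subject) per pair, each with its own sampled misalignment;
#' returns the pairs plus a manifest of seeds and ground-truth parameters.
#'
#' @param n number of pairs.
#' @param seed master seed; subject and misalignment seeds are derived
#'   from it deterministically.
#' @param shape,K passed to [generate_phantom()].
#' @param ranges passed to [sample_affine_params()].
#' @param noise_sd passed to [make_pair()].
#' @return list with `pairs` and `manifest` (data frame).
#' @export
generate_cohort <- function(n, seed = 1L, shape = c(64L, 64L, 32L), K = 5L,
                            ranges = default_param_ranges(), noise_sd = 0) {
  pairs <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- (seed * 1000L + i) %% .Machine$integer.max
    pseed <- (seed * 2000L + i) %% .Machine$integer.max
    ph <- generate_phantom(sseed, shape, K)
    par <- sample_affine_params(pseed, ranges)
    pairs[[i]] <- make_pair(ph, par, noise_sd, noise_seed = pseed + 1L)
    man[[i]] <- data.frame(pair = i, subject_seed = sseed,
                           param_seed = pseed,
                           t(as.data.frame(unclass(par))))
  }
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  list(pairs = pairs, manifest = manifest)
}
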