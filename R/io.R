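# ---------------------------------------------------------------------------
# NIfTI I/O and affine-stage preprocessing. World-space (scanner)
# coordinates are touched only here; everything downstream works in voxel
# or normalized coordinates with array axes (x, y, z) mapping to NIfTI
# i, j, k and 0-based voxel indexing.
# ---------------------------------------------------------------------------

#' Preprocessing specification for the affine stage
#'
#' @param shape target grid (default 96 x 96 x 48).
#' @param spacing target voxel spacing in mm (default 0.3 x 0.3 x 0.4).
#' @export
preproc_spec <- function(shape = c(96L, 96L, 48L),
                         spacing = c(0.3, 0.3, 0.4)) {
  if (any(shape <= 0) || any(spacing <= 0))
    stop("shape and spacing must be positive")
  list(shape = as.integer(shape), spacing = spacing)
}

#' Load a 3D volume or 4D series from a NIfTI file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return numeric array (3D or 4D) with attributes `spacing` (per-axis
#'   voxel size) and `nifti_header` preserved for round-tripping.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 4 && dim(arr)[4] == 1) { arr <- arr[, , , 1]; nd <- 3 }
  if (!nd %in% c(3, 4)) stop("expected a 3D volume or 4D series")
  attr(arr, "spacing") <- RNifti::pixdim(img)[1:3]
  attr(arr, "nifti_header") <- RNifti::niftiHeader(img)
  arr
}

#' Save a volume or series as NIfTI
#'
#' @param vol 3D/4D array; `spacing` per-axis voxel size (taken from the
#'   `spacing` attribute when present).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
save_volume <- function(vol, path, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(vol, "spacing")
  if (is.null(spacing)) spacing <- rep(1, 3)
  arr <- array(as.numeric(vol), dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(vol)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel-wise mean over the time axis of a 4D series
#'
#' Collapses an fMRI series to a representative 3D volume prior to
#' registration; the resulting single transform is then applied to every
#' frame.
#'
#' @param series 4D array with at least one frame.
#' @return 3D array.
#' @export
temporal_mean <- function(series) {
  d <- dim(series)
  if (length(d) != 4 || d[4] < 1) stop("series must be 4D with >= 1 frame")
  out <- array(rowMeans(matrix(series, prod(d[1:3]), d[4])), d[1:3])
  attr(out, "spacing") <- attr(series, "spacing")
  out
}

#' Resample to a target spacing and pad/crop to a target shape
#'
#' Trilinear resampling to the target voxel spacing followed by symmetric
#' zero padding (or cropping) to the exact target grid.
#'
#' @param vol 3D array; uses its `spacing` attribute (default unit voxels).
#' @param spec [preproc_spec()].
#' @return array of dimension `spec$shape` with `spacing = spec$spacing`.
#' @export
resample_pad <- function(vol, spec = preproc_spec()) {
  sp_in <- attr(vol, "spacing")
  if (is.null(sp_in)) sp_in <- rep(1, 3)
  new_dim <- pmax(2L, as.integer(round(dim(vol) * sp_in / spec$spacing)))
  v <- resize_volume(array(as.numeric(vol), dim(vol)), new_dim)
  out <- array(0, spec$shape)
  # symmetric placement: centre the resampled grid inside the target grid
  off_out <- pmax(0L, (spec$shape - new_dim) %/% 2L)
  off_in <- pmax(0L, (new_dim - spec$shape) %/% 2L)
  cnt <- pmin(new_dim, spec$shape)
  out[off_out[1] + seq_len(cnt[1]), off_out[2] + seq_len(cnt[2]),
      off_out[3] + seq_len(cnt[3])] <-
    v[off_in[1] + seq_len(cnt[1]), off_in[2] + seq_len(cnt[2]),
      off_in[3] + seq_len(cnt[3])]
  attr(out, "spacing") <- spec$spacing
  out
}

#' Min-max intensity normalization to [0, 1]
#'
#' @param vol 3D array. Constant volumes map to all zeros with a warning.
#' @export
normalize_intensity <- function(vol) {
  r <- range(vol)
  if (r[1] == r[2]) {
    warning("constant volume; normalized to all zeros")
    out <- array(0, dim(vol))
  } else {
    out <- (vol - r[1]) / (r[2] - r[1])
  }
  attr(out, "spacing") <- attr(vol, "spacing")
  out
}
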