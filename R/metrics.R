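# ---------------------------------------------------------------------------
# Registration evaluation over multi-structure label maps: Dice, the mean of
# the worst 30% of Dice scores, and the 95th-percentile symmetric surface
# distance.
# ---------------------------------------------------------------------------

#' Dice similarity coefficient
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)} between two voxel sets on the same
#' grid. Both sets empty is a vacuous success (1); exactly one empty gives 0.
#'
#' @param a,b logical arrays of identical shape (or coercible).
#' @return scalar in \eqn{[0, 1]}.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("label grids differ in shape")
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# boundary voxels of a mask: set voxels with a 6-neighbour outside the set
# (volume edges count as outside)
boundary_mask <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, dir) {
    s <- array(FALSE, d)
    idx_from <- lapply(d, seq_len)
    idx_to <- idx_from
    n <- d[ax]
    if (dir > 0) { idx_to[[ax]] <- 2:n; idx_from[[ax]] <- 1:(n - 1) }
    else { idx_to[[ax]] <- 1:(n - 1); idx_from[[ax]] <- 2:n }
    s <- do.call(`[<-`, c(list(s), idx_to, list(do.call(`[`, c(list(m), idx_from)))))
    acc & s
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, ax, dir)
  m & !interior
}

mask_coords <- function(m, spacing = c(1, 1, 1)) {
  w <- which(m)
  d <- dim(m)
  x <- (w - 1) %% d[1]
  y <- ((w - 1) %/% d[1]) %% d[2]
  z <- (w - 1) %/% (d[1] * d[2])
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

# chunked nearest-neighbour distances from each row of `a` to the set `b`
directed_min_dist <- function(a, b, chunk = 1000L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), nb2, `+`) - 2 * tcrossprod(aa, b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' 95th-percentile Hausdorff distance between two voxel sets
#'
#' Pools the directed boundary-to-boundary Euclidean distances in both
#' directions and takes the 95th percentile. Distances are in voxel units
#' unless a `spacing` is supplied.
#'
#' @param a,b non-empty logical arrays of identical shape.
#' @param spacing voxel spacing triple (default unit voxels).
#' @param q percentile (default 0.95; 1 gives the classical Hausdorff
#'   distance).
#' @return non-negative scalar.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1), q = 0.95) {
  if (!all(dim(a) == dim(b))) stop("label grids differ in shape")
  a <- array(as.logical(a), dim(a)); b <- array(as.logical(b), dim(b))
  if (sum(a) == 0 || sum(b) == 0)
    stop("hd95 requires two non-empty voxel sets")
  pa <- mask_coords(boundary_mask(a), spacing)
  pb <- mask_coords(boundary_mask(b), spacing)
  d <- c(directed_min_dist(pa, pb), directed_min_dist(pb, pa))
  as.numeric(stats::quantile(d, q, names = FALSE))
}

#' Mean of the lowest 30% of Dice scores
#'
#' Summarizes the worst-aligned cases: the values are sorted ascending and
#' the lowest `ceiling(0.3 n)` are averaged.
#'
#' @param per_case_dsc non-empty numeric vector of Dice scores.
#' @return scalar, never larger than `mean(per_case_dsc)`.
#' @export
dsc30 <- function(per_case_dsc) {
  n <- length(per_case_dsc)
  if (n == 0) stop("empty DSC list")
  k <- ceiling(0.3 * n)
  mean(sort(per_case_dsc)[seq_len(k)])
}

#' Evaluate a trained model on labelled test pairs
#'
#' Registers each pair, warps the moving label map with nearest-neighbour
#' interpolation, and computes per-structure Dice and (optionally) HD95
#' against the fixed labels, together with the unregistered baseline.
#' Structures empty in either map after warping are excluded from HD95 with
#' a warning.
#'
#' @param model trained model (or `NULL` to score centre-of-mass alignment
#'   only is not supported — pass an untrained model for that).
#' @param pairs list of `list(fixed, moving, fixed_labels, moving_labels)`.
#' @param compute_hd95 logical; surface distances are the expensive part.
#' @param com_init passed to [network_forward()].
#' @param spacing voxel spacing for HD95 (default voxel units).
#' @return list with `per_structure` data frame (pair, structure, dsc,
#'   dsc_unreg, hd95), `mean_dsc`, `sd_dsc`, `dsc30`, `mean_hd95`,
#'   `mean_dsc_unregistered`, `per_pair` data frame.
#' @export
evaluate_registration <- function(model, pairs, compute_hd95 = TRUE,
                                  com_init = TRUE, spacing = c(1, 1, 1)) {
  rows <- list()
  pair_rows <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    fw <- network_forward(model, pr$fixed, pr$moving, com_init = com_init)
    warped_lab <- warp_volume(pr$moving_labels, fw$transform, "nearest")
    ks <- sort(setdiff(unique(as.vector(pr$fixed_labels)), 0))
    for (k in ks) {
      fk <- pr$fixed_labels == k
      wk <- warped_lab == k
      uk <- pr$moving_labels == k
      h <- NA_real_
      if (compute_hd95) {
        if (sum(wk) == 0 || sum(fk) == 0) {
          warning(sprintf("structure %d empty after warping in pair %d; HD95 skipped",
                          k, pi))
        } else h <- hd95(fk, wk, spacing)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(pair = pi, structure = k,
                   dsc = dice(fk, wk), dsc_unreg = dice(fk, uk), hd95 = h)
    }
    prs <- do.call(rbind, rows[vapply(rows, function(r) r$pair[1] == pi, TRUE)])
    pair_rows[[pi]] <- data.frame(pair = pi,
                                  mean_dsc = mean(prs$dsc),
                                  mean_dsc_unreg = mean(prs$dsc_unreg))
  }
  per <- do.call(rbind, rows)
  per_pair <- do.call(rbind, pair_rows)
  list(per_structure = per,
       per_pair = per_pair,
       mean_dsc = mean(per$dsc),
       sd_dsc = stats::sd(per$dsc),
       dsc30 = dsc30(per$dsc),
       mean_hd95 = if (all(is.na(per$hd95))) NA_real_ else
         mean(per$hd95, na.rm = TRUE),
       mean_dsc_unregistered = mean(per$dsc_unreg))
}

#' Write an evaluation report as CSV + JSON summary
#'
#' @param report from [evaluate_registration()].
#' @param csv_path per-structure CSV; `json_path` summary JSON.
#' @export
write_eval_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$per_structure, csv_path, row.names = FALSE)
  jsonlite::write_json(list(mean_dsc = report$mean_dsc,
                            sd_dsc = report$sd_dsc,
                            dsc30 = report$dsc30,
                            mean_hd95 = report$mean_hd95,
                            mean_dsc_unregistered = report$mean_dsc_unregistered),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
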