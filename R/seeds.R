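#' Default seed regions
#'
#' Centres (MNI mm, RAS) of the five 4-mm spherical seeds used throughout:
#' dorsolateral prefrontal cortex (DLPFC), ventromedial prefrontal cortex
#' (vmPFC), dorsal anterior cingulate cortex (dACC), insula, and striatum.
#'
#' @return data.frame with `name`, `x`, `y`, `z` (mm) and `radius` (mm).
#' @export
default_seeds <- function() {
  data.frame(name = c("DLPFC", "vmPFC", "dACC", "Insula", "Striatum"),
             x = c(44, -6, -4, 34, 18),
             y = c(32, 46, 20, 22, 12),
             z = c(36, -6, 46, 0, 0),
             radius = 4,
             stringsAsFactors = FALSE)
}

#' Voxelize a spherical seed
#'
#' Returns the linear indices of all voxels whose centres lie within
#' `radius` mm (Euclidean, via the grid affine) of the seed centre. The
#' centre must lie inside the grid's bounding box; an empty result is a
#' geometry error.
#'
#' @param center_mm Length-3 mm coordinates of the sphere centre.
#' @param radius Sphere radius in mm.
#' @param grid An [fc_grid()].
#' @param name Seed label used in error messages.
#' @return Integer vector of linear voxel indices (column-major).
#' @export
voxelize_seed <- function(center_mm, radius, grid, name = "seed") {
  stopifnot(length(center_mm) == 3L, radius >= 0)
  vox <- drop(mm_to_voxel(grid, center_mm))
  if (any(vox < 0.5) || any(vox > grid$dim + 0.5))
    abort_arg("seed '", name, "' centre lies outside the grid")
  # candidate box around the centre, then exact distance test
  half <- ceiling(radius / grid$voxel_mm) + 1L
  rng <- lapply(1:3, function(a)
    max(1L, floor(vox[a]) - half):min(grid$dim[a], ceiling(vox[a]) + half))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- voxel_to_mm(grid, ijk)
  d2 <- colSums((t(mm) - center_mm)^2)
  keep <- d2 <= radius^2 + 1e-9
  if (!any(keep))
    abort_arg("seed '", name, "' contains no voxels at radius ", radius, " mm")
  sort(ijk[keep, 1] +
         (ijk[keep, 2] - 1L) * grid$dim[1] +
         (ijk[keep, 3] - 1L) * grid$dim[1] * grid$dim[2])
}

#' Seed mean percent-signal-change series
#'
#' Converts each seed voxel's residual series to percent signal change
#' relative to that voxel's raw (pre-residualization) mean over the run,
#' then averages across seed voxels per volume.
#'
#' @param residuals Volumes x voxels residual matrix for one run.
#' @param raw Volumes x voxels raw signal matrix for the same run (used for
#'   the PSC reference means).
#' @param seed_voxels Linear voxel indices from [voxelize_seed()].
#' @return Numeric vector, one value per volume.
#' @export
seed_series <- function(residuals, raw, seed_voxels) {
  if (length(seed_voxels) == 0L) abort_arg("empty seed")
  ref <- colMeans(raw[, seed_voxels, drop = FALSE])
  if (any(ref <= 0)) abort_arg("non-positive raw reference mean in seed")
  # residuals are deviations already, so PSC is 100 * residual / raw mean
  psc <- 100 * sweep(residuals[, seed_voxels, drop = FALSE], 2, ref, "/")
  rowMeans(psc)
}

#' Voxelwise Fisher-z connectivity map for one seed series
#'
#' Pearson correlation between the seed series and every voxel's residual
#' series, then `z = atanh(r)` with `r` clamped to +/-(1 - 1e-7). Voxels
#' with zero variance get `z = 0` with a warning; a zero-variance seed
#' series is an error.
#'
#' @param seed_ts Seed series (length = volumes).
#' @param residuals Volumes x voxels residual matrix.
#' @return Numeric vector of Fisher z values, one per voxel.
#' @export
connectivity_zmap <- function(seed_ts, residuals) {
  if (length(seed_ts) != nrow(residuals))
    abort_arg("seed series length != number of volumes")
  if (stats::sd(seed_ts) == 0) abort_arg("seed series has zero variance")
  s <- seed_ts - mean(seed_ts)
  Y <- sweep(residuals, 2, colMeans(residuals))
  sy <- sqrt(colSums(Y^2))
  zero <- sy == 0
  sy[zero] <- 1
  r <- as.vector(crossprod(Y, s)) / (sqrt(sum(s^2)) * sy)
  if (any(zero)) {
    warning(sum(zero), " zero-variance voxel(s): z set to 0")
    r[zero] <- 0
  }
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r)))
}
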