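#' Define the simulation/analysis voxel grid
#'
#' A light-weight geometry object: voxel dimensions, isotropic voxel size,
#' an RAS mm affine (voxel index 1,1,1 maps to `origin_mm`), repetition time,
#' and schematic tissue masks. The default 30 x 36 x 30 grid of 3 mm voxels
#' is centred so that all default seed centres (MNI mm, see
#' [default_seeds()]) fall inside it.
#'
#' The tissue masks are deliberately schematic: a small block in one corner
#' stands in for CSF (ventricles) and a shell near another face for white
#' matter. They exist so that tissue mean signals and their regressors are
#' exercised end to end, not to emulate anatomy.
#'
#' @param dim Integer vector of 3 voxel counts.
#' @param voxel_mm Isotropic voxel edge length in mm.
#' @param origin_mm mm coordinates (RAS) of the centre of voxel (1,1,1).
#' @param tr Repetition time in seconds.
#' @param csf_mask,wm_mask Optional logical arrays of dimension `dim`;
#'   defaults carve schematic blocks.
#' @return An object of class `fc_grid`.
#' @export
fc_grid <- function(dim = c(30L, 36L, 30L), voxel_mm = 3,
                    origin_mm = c(-40.5, -55.5, -40.5), tr = 2,
                    csf_mask = NULL, wm_mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), voxel_mm > 0, tr > 0,
            length(origin_mm) == 3L)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- origin_mm - voxel_mm  # mm = affine %*% c(i,j,k,1), 1-based
  if (is.null(csf_mask)) {
    csf_mask <- array(FALSE, dim)
    n <- pmax(1L, dim %/% 8L)
    csf_mask[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- TRUE
  }
  if (is.null(wm_mask)) {
    wm_mask <- array(FALSE, dim)
    n <- pmax(1L, dim %/% 8L)
    wm_mask[dim[1] - seq_len(n[1]) + 1L, seq_len(n[2]), seq_len(n[3])] <- TRUE
  }
  stopifnot(identical(dim(csf_mask), dim), identical(dim(wm_mask), dim))
  structure(list(dim = dim, voxel_mm = voxel_mm, affine = affine, tr = tr,
                 csf_mask = csf_mask, wm_mask = wm_mask),
            class = "fc_grid")
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %d x %d x %d voxels @ %g mm, TR %g s\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm, x$tr))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dim)

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param grid An `fc_grid`.
#' @param ijk Matrix (n x 3) or vector of 1-based voxel indices.
#' @return Matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  t(grid$affine %*% t(cbind(ijk, 1)))[, 1:3, drop = FALSE]
}

#' Convert mm coordinates to continuous 1-based voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param mm Matrix (n x 3) or vector of mm coordinates.
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- rbind2mat(mm)
  t(solve(grid$affine) %*% t(cbind(mm, 1)))[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' All voxel centre coordinates of a grid, in mm
#' @param grid An `fc_grid`.
#' @return Matrix (n_voxels x 3), rows in array (column-major) order.
#' @export
grid_coordinates_mm <- function(grid) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid$dim[1]),
                               j = seq_len(grid$dim[2]),
                               k = seq_len(grid$dim[3])))
  voxel_to_mm(grid, ijk)
}

# --- separable Gaussian smoothing ------------------------------------------

# Dense 1-D Gaussian smoothing matrix (rows sum to 1) for n points at unit
# spacing and kernel sd `sigma` (in points). sigma = 0 returns the identity.
gaussian_smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Apply matrix K along dimension `along` of a 3- or 4-D array.
tensor_apply <- function(x, K, along) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(along, setdiff(seq_len(nd), along))
  y <- aperm(x, perm)
  dy <- dim(y)
  y <- K %*% matrix(y, nrow = d[along])
  dim(y) <- dy
  aperm(y, order(perm))
}

#' Smooth a 3-D or 4-D array with a separable Gaussian kernel
#'
#' Smoothing acts on the three spatial dimensions only; for a 4-D array the
#' fourth dimension (time) is untouched.
#'
#' @param x 3-D or 4-D numeric array.
#' @param fwhm_mm Kernel full width at half maximum in mm (scalar, isotropic).
#' @param voxel_mm Voxel edge length in mm.
#' @return Array of the same dimension.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(x)
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  d <- dim(x)
  for (ax in 1:3) x <- tensor_apply(x, gaussian_smoothing_matrix(d[ax], sigma), ax)
  x
}

# Per-voxel standard-deviation map of separably smoothed unit-variance white
# noise: sd(i,j,k) = sqrt( r_x[i] * r_y[j] * r_z[k] ) with r = rowSums(K^2).
smoothed_noise_sd_map <- function(dim, fwhm_mm, voxel_mm) {
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  r <- lapply(dim, function(n) {
    K <- gaussian_smoothing_matrix(n, sigma)
    rowSums(K^2)
  })
  sqrt(outer(outer(r[[1]], r[[2]]), r[[3]]))
}
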