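#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' changes of the three translations (mm) plus the three rotations (radians)
#' converted to arc length on a sphere of radius `head_radius`. The first
#' frame has FD 0 by convention.
#'
#' @param motion Matrix with one row per volume and 6 columns: translations
#'   x, y, z in mm then rotations x, y, z in radians.
#' @param head_radius Sphere radius in mm used to convert rotations.
#' @return Numeric vector of FD values (mm), one per volume.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 1L || ncol(motion) != 6L)
    abort_arg("motion must be a non-empty matrix with 6 columns")
  d <- abs(temporal_derivative(motion))
  rowSums(d[, 1:3, drop = FALSE]) + head_radius * rowSums(d[, 4:6, drop = FALSE])
}

# Accept a 4-D array (x,y,z,t) or a t x voxels matrix plus a mask/column set.
as_time_by_voxel <- function(bold, mask = NULL) {
  if (inherits(bold, "fc_bold")) bold <- bold$data
  if (is.array(bold) && length(dim(bold)) == 4L) {
    d <- dim(bold)
    m <- t(matrix(bold, nrow = prod(d[1:3]), ncol = d[4]))
    if (!is.null(mask)) {
      idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
      m <- m[, idx, drop = FALSE]
    }
    m
  } else {
    m <- as.matrix(bold)
    if (!is.null(mask)) {
      idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
      m <- m[, idx, drop = FALSE]
    }
    m
  }
}

#' Standardized DVARS of a BOLD run
#'
#' Raw DVARS at volume t is the root mean square, over the mask, of the
#' voxelwise signal change from volume t-1; the first volume is 0. The
#' series is standardized by dividing by its within-run median over volumes
#' 2..T (the scaling is configurable via `center`), so a non-degenerate run
#' has median standardized DVARS 1.
#'
#' @param bold 4-D array (x,y,z,t), `fc_bold`, or t x voxels matrix.
#' @param mask Logical array or voxel index vector; must be non-empty.
#' @param center `"median"` (default) or `"mean"`: the within-run statistic
#'   used for standardization.
#' @return Numeric vector, one value per volume.
#' @export
standardized_dvars <- function(bold, mask = NULL, center = c("median", "mean")) {
  center <- match.arg(center)
  if (!is.null(mask) && sum(if (is.logical(mask)) mask else length(mask)) == 0)
    abort_arg("mask is empty")
  m <- as_time_by_voxel(bold, mask)
  if (ncol(m) == 0L) abort_arg("mask is empty")
  d <- diff(m)
  raw <- c(0, sqrt(rowMeans(d^2)))
  scale_by <- if (center == "median") stats::median(raw[-1]) else mean(raw[-1])
  if (length(raw) == 1L || !is.finite(scale_by) || scale_by == 0) return(raw)
  raw / scale_by
}

#' Mean tissue signals per volume
#'
#' Unweighted mean over each mask, per volume: CSF, white matter and
#' whole-brain ("global") signals.
#'
#' @inheritParams standardized_dvars
#' @param csf_mask,wm_mask,whole_mask Logical arrays or index vectors; each
#'   must be non-empty.
#' @return data.frame with columns `csf`, `white_matter`, `global_signal`.
#' @export
tissue_mean_signals <- function(bold, csf_mask, wm_mask, whole_mask) {
  one <- function(mask, label) {
    idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
    if (length(idx) == 0L) abort_arg("empty mask: ", label)
    rowMeans(as_time_by_voxel(bold, idx))
  }
  data.frame(csf = one(csf_mask, "csf"),
             white_matter = one(wm_mask, "white_matter"),
             global_signal = one(whole_mask, "whole_brain"))
}

#' Assemble the expanded confounds table
#'
#' Emits the full nuisance set consumed by the first-level model: the six
#' motion parameters, their temporal derivatives, and quadratics of both
#' (24 columns); the three tissue signals and their derivatives; framewise
#' displacement; standardized DVARS; and per-volume motion-outlier flags,
#' true when FD exceeds `fd_thresh` mm or standardized DVARS exceeds
#' `dvars_thresh`. First-row derivatives are 0 so row counts stay aligned.
#'
#' @param motion t x 6 motion matrix (see [framewise_displacement()]).
#' @param fd FD series (mm).
#' @param dvars Standardized DVARS series.
#' @param tissue data.frame from [tissue_mean_signals()].
#' @param fd_thresh,dvars_thresh Outlier thresholds.
#' @return data.frame with one row per volume.
#' @export
expand_confounds <- function(motion, fd, dvars, tissue,
                             fd_thresh = 0.5, dvars_thresh = 1.5) {
  motion <- as.matrix(motion)
  n <- nrow(motion)
  if (length(fd) != n || length(dvars) != n || nrow(tissue) != n)
    abort_arg("all confound series must have the same number of volumes")
  mot_names <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  colnames(motion) <- mot_names
  dmot <- temporal_derivative(motion)
  out <- data.frame(motion, check.names = FALSE)
  out[paste0(mot_names, "_derivative1")] <- as.data.frame(dmot)
  out[paste0(mot_names, "_power2")] <- as.data.frame(motion^2)
  out[paste0(mot_names, "_derivative1_power2")] <- as.data.frame(dmot^2)
  for (nm in names(tissue)) {
    out[[nm]] <- tissue[[nm]]
    out[[paste0(nm, "_derivative1")]] <- temporal_derivative(tissue[[nm]])
  }
  out$framewise_displacement <- fd
  out$std_dvars <- dvars
  out$motion_outlier <- fd > fd_thresh | dvars > dvars_thresh
  out
}

# Column names of the motion block (6 + 6 + 12 = 24 columns).
motion_block_columns <- function() {
  mot <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  c(mot, paste0(mot, "_derivative1"), paste0(mot, "_power2"),
    paste0(mot, "_derivative1_power2"))
}

#' Simulate a head-motion series
#'
#' Random-walk translations/rotations with occasional spikes, so that FD and
#' DVARS outlier flags are exercised downstream.
#'
#' @param n_vols Number of volumes.
#' @param walk_sd_mm,walk_sd_rad Per-step random-walk SDs.
#' @param spike_prob Per-volume probability of a motion spike.
#' @param spike_mm Spike magnitude (mm, split across axes).
#' @param rng_seed Integer seed.
#' @return t x 6 matrix (translations mm, rotations rad).
#' @export
simulate_motion <- function(n_vols = 140, walk_sd_mm = 0.02,
                            walk_sd_rad = 4e-4, spike_prob = 0.015,
                            spike_mm = 0.45, rng_seed = NULL) {
  with_rng_seed(rng_seed, {
    steps <- cbind(matrix(stats::rnorm(n_vols * 3, 0, walk_sd_mm), n_vols),
                   matrix(stats::rnorm(n_vols * 3, 0, walk_sd_rad), n_vols))
    spikes <- stats::runif(n_vols) < spike_prob
    steps[spikes, 1] <- steps[spikes, 1] +
      spike_mm * sign(stats::rnorm(sum(spikes)))
    m <- apply(steps, 2, cumsum)
    m[1, ] <- 0
    dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                                "rot_x", "rot_y", "rot_z"))
    m
  })
}
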