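#' Ground-truth coupling plant for the BOLD simulator
#'
#' Encodes what the analysis is built to recover: the stable task response
#' is time-invariant (so the first-level model absorbs it completely), while
#' a latent fluctuation shared between a seed region and a target region
#' carries the fatigue signal in the error term. The seed-target correlation
#' of the latent components in a run is
#' `tanh(coupling_intercept + slope(condition) * fatigue)`, with `fatigue`
#' the run's covariate value; intercept and slopes are therefore on the
#' Fisher-z scale (z units per covariate unit), so the voxelwise
#' interaction slope estimated downstream has the planted value as its
#' estimand. The `tanh` link keeps every attainable planted correlation
#' strictly inside (-1, 1); non-finite coupling values are refused at
#' simulation time.
#'
#' @param seed_region,target_region,task_region Linear voxel index vectors
#'   (possibly `NULL` for no plant / no activation).
#' @param coupling_intercept Fisher-z intercept of the planted coupling.
#' @param coupling_slope_2back,coupling_slope_0back Fisher-z change per
#'   covariate unit, by condition.
#' @param latent_sd Amplitude (signal units) of the latent fluctuations
#'   added to the seed and target regions.
#' @param latent_ar Lag-1 autocorrelation of the latent fluctuations.
#' @param task_amplitude Height of the stable task response in `task_region`.
#' @param noise_sd Voxel noise SD (signal units) after smoothing.
#' @param smoothing_fwhm Spatial smoothness of the noise field (mm).
#' @param drift_coeffs Per-run polynomial drift coefficients (Legendre
#'   orders 1..length), signal units.
#' @param motion_coupling_sd SD of per-voxel weights tying the signal to the
#'   six motion parameters.
#' @param global_sd,csf_sd,wm_sd Amplitudes of shared "physiological"
#'   fluctuations added to all voxels / the CSF block / the WM block.
#' @param baseline Mean signal level (keeps PSC references positive).
#' @export
plant_spec <- function(seed_region = NULL, target_region = NULL,
                       task_region = NULL,
                       coupling_intercept = 0.1,
                       coupling_slope_2back = 0.3,
                       coupling_slope_0back = 0,
                       latent_sd = 1, latent_ar = 0.4,
                       task_amplitude = 2, noise_sd = 0.6,
                       smoothing_fwhm = 6,
                       drift_coeffs = c(1.2, -0.8),
                       motion_coupling_sd = 0.3,
                       global_sd = 0.5, csf_sd = 0.7, wm_sd = 0.4,
                       baseline = 1000) {
  structure(list(seed_region = seed_region, target_region = target_region,
                 task_region = task_region,
                 coupling_intercept = coupling_intercept,
                 coupling_slope_2back = coupling_slope_2back,
                 coupling_slope_0back = coupling_slope_0back,
                 latent_sd = latent_sd, latent_ar = latent_ar,
                 task_amplitude = task_amplitude, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm, drift_coeffs = drift_coeffs,
                 motion_coupling_sd = motion_coupling_sd,
                 global_sd = global_sd, csf_sd = csf_sd, wm_sd = wm_sd,
                 baseline = baseline),
            class = "fc_plant")
}

# Planted seed-target correlation for one run.
planted_correlation <- function(plant, condition, fatigue) {
  slope <- if (condition == "2-back") plant$coupling_slope_2back
           else plant$coupling_slope_0back
  zeta <- plant$coupling_intercept + slope * fatigue
  if (!is.finite(zeta))
    abort_arg("planted coupling is not finite at fatigue = ", fatigue)
  # the tanh link keeps |r| < 1 analytically; clamp where tanh saturates in
  # floating point
  r <- tanh(zeta)
  if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
  r
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, phi) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * e[t]
  x
}

#' Simulate one BOLD run with its confounds
#'
#' Signal model per voxel: baseline + stable task activation (trial onsets
#' convolved with the canonical HRF, constant amplitude, in the task
#' region) + per-run polynomial drift + motion-coupled components + shared
#' global/CSF/WM fluctuations + latent seed-target coupling (see
#' [plant_spec()]) + independent Gaussian noise smoothed to
#' `smoothing_fwhm` and rescaled to marginal SD `noise_sd`. The returned
#' confounds table is computed from the emitted data and the true motion
#' series by the confound-metric functions, exactly as a real run would be
#' processed.
#'
#' @param schedule An `fc_schedule` for the run.
#' @param fatigue The run's fatigue covariate value (drives the planted
#'   coupling).
#' @param plant A [plant_spec()].
#' @param grid An [fc_grid()].
#' @param n_vols Volumes per run.
#' @param rng_seed Integer seed; the run is a pure function of it.
#' @param hrf See [hrf_spec()].
#' @return List with `bold` (an `fc_bold`: 4-D data + grid), `confounds`
#'   (expanded table), `motion` (t x 6 matrix) and `truth` (latent series
#'   and planted correlation, for recovery checks).
#' @export
simulate_bold <- function(schedule, fatigue = 0, plant = plant_spec(),
                          grid = fc_grid(), n_vols = 140, rng_seed = NULL,
                          hrf = hrf_spec()) {
  nv <- n_voxels(grid)
  for (rg in c("seed_region", "target_region", "task_region")) {
    idx <- plant[[rg]]
    if (!is.null(idx) && (length(idx) > 0) &&
        (min(idx) < 1 || max(idx) > nv))
      abort_arg(rg, " lies outside the grid")
  }
  r_plant <- planted_correlation(plant, schedule$condition, fatigue)

  with_rng_seed(rng_seed, {
    motion <- simulate_motion(n_vols)
    task_ts <- task_regressor(schedule, n_vols = n_vols, tr = grid$tr,
                              hrf = hrf)

    # time x voxel signal built in matrix form
    sig <- matrix(plant$baseline, n_vols, nv)
    if (!is.null(plant$task_region) && plant$task_amplitude != 0)
      sig[, plant$task_region] <- sig[, plant$task_region] +
        plant$task_amplitude * task_ts
    if (length(plant$drift_coeffs)) {
      drift_ts <- legendre_basis(n_vols, length(plant$drift_coeffs))[, -1,
                   drop = FALSE] %*% plant$drift_coeffs
      sig <- sig + as.vector(drift_ts)
    }
    if (plant$motion_coupling_sd > 0) {
      W <- matrix(stats::rnorm(6 * nv, 0, plant$motion_coupling_sd), 6, nv)
      sig <- sig + motion %*% W
    }
    if (plant$global_sd > 0)
      sig <- sig + plant$global_sd * ar1_series(n_vols, 0.5)
    if (plant$csf_sd > 0 && any(grid$csf_mask))
      sig[, which(grid$csf_mask)] <- sig[, which(grid$csf_mask)] +
        plant$csf_sd * ar1_series(n_vols, 0.5)
    if (plant$wm_sd > 0 && any(grid$wm_mask))
      sig[, which(grid$wm_mask)] <- sig[, which(grid$wm_mask)] +
        plant$wm_sd * ar1_series(n_vols, 0.5)

    truth <- list(planted_r = r_plant, fatigue = fatigue,
                  condition = schedule$condition)
    if (!is.null(plant$seed_region) && !is.null(plant$target_region) &&
        plant$latent_sd > 0) {
      u <- ar1_series(n_vols, plant$latent_ar)
      u2 <- ar1_series(n_vols, plant$latent_ar)
      v <- r_plant * u + sqrt(1 - r_plant^2) * u2
      sig[, plant$seed_region] <- sig[, plant$seed_region] +
        plant$latent_sd * u
      sig[, plant$target_region] <- sig[, plant$target_region] +
        plant$latent_sd * v
      truth$latent_seed <- plant$latent_sd * u
      truth$latent_target <- plant$latent_sd * v
    }
    if (plant$noise_sd > 0) {
      eps <- array(stats::rnorm(nv * n_vols), c(grid$dim, n_vols))
      if (plant$smoothing_fwhm > 0) {
        eps <- smooth_gaussian(eps, plant$smoothing_fwhm, grid$voxel_mm)
        sdmap <- smoothed_noise_sd_map(grid$dim, plant$smoothing_fwhm,
                                       grid$voxel_mm)
        eps <- eps / as.vector(sdmap)  # recycles over the 4th dim
      }
      sig <- sig + plant$noise_sd * t(matrix(eps, nv, n_vols))
    }

    bold <- structure(list(data = array(t(sig), c(grid$dim, n_vols)),
                           grid = grid, tr = grid$tr),
                      class = "fc_bold")
    fd <- framewise_displacement(motion)
    dv <- standardized_dvars(sig, mask = NULL)
    tissue <- tissue_mean_signals(sig, grid$csf_mask, grid$wm_mask,
                                  mask_all <- rep(TRUE, nv))
    confounds <- expand_confounds(motion, fd, dv, tissue)
    list(bold = bold, confounds = confounds, motion = motion, truth = truth)
  })
}

#' @export
print.fc_bold <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fc_bold> %d x %d x %d voxels, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

# time x voxel matrix view of an fc_bold
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, prod(d[1:3]), d[4]))
}
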