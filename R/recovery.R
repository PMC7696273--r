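#' Parameter-recovery experiment for the planted fatigue coupling
#'
#' Runs replicate synthetic studies in which only the 2-back condition
#' carries a fatigue-coupling slope, pushes each through the full pipeline
#' (simulation, deconvolution GLM, seed connectivity, voxelwise
#' mixed-effects), and asks two questions per replicate: does the
#' interaction map's peak |t| fall inside the planted target region, and
#' does the 95% CI of the slope at the target-centre voxel cover the
#' planted value? The slope is read at the target-centre voxel (the
#' location that defines the plant) rather than at the selected peak, so
#' the check is free of winner's-curse selection bias.
#'
#' The experiment grid is a compact 12^3 box with one seed/target pair;
#' the plant uses a low noise level (`noise_sd = 0.15` against unit latent
#' amplitude) so that correlation attenuation by voxel noise is negligible
#' relative to the slope's standard error and the planted Fisher-z slope
#' is the estimand.
#'
#' @param n_reps Number of replicate datasets.
#' @param n_subjects Subjects per replicate (one group).
#' @param slope_2back Planted 2-back Fisher-z slope per covariate unit.
#' @param rng_seed Master seed.
#' @param n_vols Volumes per run.
#' @return data.frame, one row per replicate: `peak_in_target`,
#'   `ci_covers`, `est`, `se`, `df`, `peak_voxel`.
#' @export
run_recovery_experiment <- function(n_reps = 20, n_subjects = 20,
                                    slope_2back = 0.3, rng_seed = 101,
                                    n_vols = 140) {
  grid <- fc_grid(dim = c(12L, 12L, 12L), origin_mm = c(0, 0, 0))
  seed_ctr <- drop(voxel_to_mm(grid, c(4, 6, 6)))
  target_ctr <- drop(voxel_to_mm(grid, c(9, 6, 6)))
  task_ctr <- drop(voxel_to_mm(grid, c(6, 6, 3)))
  plant <- plant_spec(
    seed_region = voxelize_seed(seed_ctr, 4, grid, "seed"),
    target_region = voxelize_seed(target_ctr, 5, grid, "target"),
    task_region = voxelize_seed(task_ctr, 8, grid, "task"),
    coupling_intercept = 0.1, coupling_slope_2back = slope_2back,
    coupling_slope_0back = 0, noise_sd = 0.15)
  target_center_vox <- which.min(colSums(
    (t(grid_coordinates_mm(grid)) - target_ctr)^2))

  out <- lapply(seq_len(n_reps), function(rep) {
    r <- recovery_replicate(derive_seed(rng_seed, rep), n_subjects, plant,
                            grid, target_center_vox, n_vols)
    r$replicate <- rep
    r
  })
  res <- do.call(rbind, out)
  res$planted <- slope_2back
  res
}

recovery_replicate <- function(seed, n_subjects, plant, grid,
                               target_center_vox, n_vols) {
  cohort <- generate_cohort(n_subjects, 0, rng_seed = derive_seed(seed, 1))
  schedules <- lapply(stats::setNames(nm = c("0-back", "2-back")),
    function(cond) lapply(1:4, function(r)
      generate_task_schedule(cond, r,
        rng_seed = derive_seed(seed, 2, match(cond, c("0-back", "2-back")), r))))
  vasf <- generate_vasf(cohort, rng_seed = derive_seed(seed, 3))
  rf <- compute_run_fatigue(vasf)
  rf$fatigue_plant <- as.numeric(scale(rf$run_mean))

  zrows <- list(); meta <- list()
  for (i in seq_len(n_subjects)) {
    for (cond in c("0-back", "2-back")) {
      runs <- lapply(1:4, function(r) {
        fat <- rf$fatigue_plant[rf$subject_id == cohort$subject_id[i] &
                                rf$condition == cond & rf$run_index == r]
        simulate_bold(schedules[[cond]][[r]], fatigue = fat, plant = plant,
                      grid = grid, n_vols = n_vols,
                      rng_seed = derive_seed(seed, 10, i,
                        match(cond, c("0-back", "2-back")), r))
      })
      Y <- do.call(rbind, lapply(runs, function(x) bold_matrix(x$bold)))
      design <- build_design(schedules[[cond]],
                             lapply(runs, `[[`, "confounds"),
                             n_vols = n_vols, tr = grid$tr, drift_order = 1)
      fitted <- fit_glm(Y, design)
      for (r in 1:4) {
        rows <- (r - 1) * n_vols + seq_len(n_vols)
        ts <- seed_series(fitted$residuals[rows, , drop = FALSE],
                          Y[rows, , drop = FALSE], plant$seed_region)
        zrows[[length(zrows) + 1L]] <-
          connectivity_zmap(ts, fitted$residuals[rows, , drop = FALSE])
        meta[[length(meta) + 1L]] <- data.frame(
          subject_id = cohort$subject_id[i], condition = cond,
          run_index = r, stringsAsFactors = FALSE)
      }
    }
  }
  Z <- do.call(rbind, zrows)
  md <- do.call(rbind, meta)
  md$key <- paste(md$subject_id, md$condition, md$run_index)
  rf$key <- paste(rf$subject_id, rf$condition, rf$run_index)
  md$fatigue_c <- rf$fatigue_plant[match(md$key, rf$key)]
  md$fatigue_c <- md$fatigue_c - mean(md$fatigue_c)
  sm <- voxelwise_fatigue_lme(Z, md)
  peak <- which.max(abs(sm$tstat))
  est <- sm$est[target_center_vox]
  se <- sm$se[target_center_vox]
  hw <- stats::qt(0.975, sm$df[target_center_vox]) * se
  data.frame(peak_in_target = peak %in% plant$target_region,
             ci_covers = abs(est - plant$coupling_slope_2back) <= hw,
             est = est, se = se, df = sm$df[target_center_vox],
             peak_voxel = peak)
}
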