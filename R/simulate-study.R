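#' Build the study analysis grid for a configuration
#'
#' The canonical grid is 30 x 36 x 30 voxels of 3 mm (see [fc_grid()]).
#' For smaller desk-scale grids the box is re-centred on the bounding box
#' of the five seed centres so that every seed stays inside; a grid too
#' small to contain the seeds is a configuration error.
#'
#' @param grid_dim Integer vector of 3 voxel counts.
#' @param voxel_mm Voxel size (mm).
#' @return An [fc_grid()].
#' @export
study_grid <- function(grid_dim = c(30L, 36L, 30L), voxel_mm = 3) {
  grid_dim <- as.integer(grid_dim)
  if (identical(grid_dim, c(30L, 36L, 30L)) && voxel_mm == 3) {
    g <- fc_grid()
  } else {
    seeds <- default_seeds()
    ctr <- c(mean(range(seeds$x)), mean(range(seeds$y)), mean(range(seeds$z)))
    origin <- ctr - (grid_dim - 1) / 2 * voxel_mm
    g <- fc_grid(dim = grid_dim, voxel_mm = voxel_mm, origin_mm = origin)
  }
  seeds <- default_seeds()
  for (i in seq_len(nrow(seeds))) {
    vox <- drop(mm_to_voxel(g, c(seeds$x[i], seeds$y[i], seeds$z[i])))
    if (any(vox < 0.5) || any(vox > g$dim + 0.5))
      abort_arg("grid_dim ", paste(grid_dim, collapse = "x"),
                " does not contain seed ", seeds$name[i])
  }
  g
}

#' Ground-truth plant for a configuration
#'
#' The planted seed region is the configured seed's 4-mm sphere; the
#' planted target is a 5-mm sphere 18 mm medial (toward -x) of it; the
#' stable task-activation region is a 12-mm sphere at the grid centre.
#'
#' @param config See [default_config()].
#' @param grid The [study_grid()] for the config.
#' @return A [plant_spec()].
#' @export
plant_from_config <- function(config, grid) {
  seeds <- default_seeds()
  s <- seeds[seeds$name == config$plant_seed_name, ]
  if (nrow(s) != 1) abort_arg("unknown plant_seed_name: ", config$plant_seed_name)
  ctr_vox <- (grid$dim + 1) / 2
  ctr_mm <- drop(voxel_to_mm(grid, ctr_vox))
  args <- config$plant
  args$seed_region <- voxelize_seed(c(s$x, s$y, s$z), s$radius, grid, s$name)
  args$target_region <- voxelize_seed(c(s$x - 18, s$y, s$z), 5, grid,
                                      paste0(s$name, "-target"))
  args$task_region <- voxelize_seed(ctr_mm, 12, grid, "task")
  do.call(plant_spec, args)
}

#' Generate the behavioral side of a study
#'
#' Cohort, shared run schedules, VAS-F ratings, run-level fatigue (with
#' Box-Cox transform and the standardized planting covariate), and task
#' performance. The planting covariate `fatigue_plant` is the z-scored raw
#' run mean over all runs; the planted coupling slopes are expressed per
#' unit of this covariate.
#'
#' @param config See [default_config()].
#' @return List: `cohort`, `schedules` (condition -> list of 4),
#'   `vasf`, `run_fatigue`, `behavior`.
#' @export
simulate_study_tables <- function(config = default_config()) {
  seed <- config$rng_seed
  cohort <- generate_cohort(config$n_ms, config$n_hc,
                            rng_seed = derive_seed(seed, 1))
  schedules <- lapply(stats::setNames(nm = c("0-back", "2-back")),
    function(cond) {
      lapply(1:4, function(r)
        generate_task_schedule(cond, r,
          rng_seed = derive_seed(seed, 2, match(cond, c("0-back", "2-back")), r)))
    })
  vasf <- generate_vasf(cohort, rng_seed = derive_seed(seed, 3))
  rf <- compute_run_fatigue(vasf)
  rf <- add_transformed_fatigue(rf)
  rf$group <- cohort$group[match(rf$subject_id, cohort$subject_id)]
  mu <- mean(rf$run_mean); sdv <- stats::sd(rf$run_mean)
  rf$fatigue_plant <- if (sdv > 0) (rf$run_mean - mu) / sdv else rf$run_mean * 0
  behavior <- generate_behavior(cohort, rf, rng_seed = derive_seed(seed, 4))
  list(cohort = cohort, schedules = schedules, vasf = vasf,
       run_fatigue = rf, behavior = behavior)
}

#' Simulate one subject and reduce to per-run seed connectivity maps
#'
#' Streams the heavy stage: for each condition the four runs are
#' simulated, the deconvolution GLM is fitted over the concatenated runs,
#' and each run's residual block is reduced to one Fisher-z map per seed.
#' The BOLD volumes are discarded after use.
#'
#' @param subject_index Row of the cohort.
#' @param tables Output of [simulate_study_tables()].
#' @param config,grid,plant Study configuration and geometry.
#' @param seed_voxels Named list: seed name -> linear voxel indices.
#' @return List: `z` (maps x voxels matrix), `meta` (one row per map),
#'   `resid_example` (residual matrix of the last condition, for
#'   smoothness estimation), `ortho_max` (max |design' residual|).
#' @export
simulate_subject_maps <- function(subject_index, tables, config, grid, plant,
                                  seed_voxels) {
  subj <- tables$cohort[subject_index, ]
  rf <- tables$run_fatigue
  zrows <- list(); meta <- list(); resid_example <- NULL; ortho <- 0
  for (cond in c("0-back", "2-back")) {
    scheds <- tables$schedules[[cond]]
    runs <- lapply(1:4, function(r) {
      fat <- rf$fatigue_plant[rf$subject_id == subj$subject_id &
                              rf$condition == cond & rf$run_index == r]
      simulate_bold(scheds[[r]], fatigue = fat, plant = plant, grid = grid,
                    rng_seed = derive_seed(config$rng_seed, 10, subject_index,
                                           match(cond, c("0-back", "2-back")), r))
    })
    Y <- do.call(rbind, lapply(runs, function(x) bold_matrix(x$bold)))
    design <- build_design(scheds, lapply(runs, `[[`, "confounds"),
                           n_vols = 140, tr = grid$tr,
                           drift_order = config$drift_order)
    fitted <- fit_glm(Y, design)
    ortho <- max(ortho, max(abs(crossprod(design$X, fitted$residuals))) /
                          nrow(Y))
    for (r in 1:4) {
      rows <- (r - 1) * 140 + seq_len(140)
      raw_r <- Y[rows, , drop = FALSE]
      res_r <- fitted$residuals[rows, , drop = FALSE]
      for (sn in names(seed_voxels)) {
        ts <- seed_series(res_r, raw_r, seed_voxels[[sn]])
        zrows[[length(zrows) + 1L]] <- connectivity_zmap(ts, res_r)
        meta[[length(meta) + 1L]] <- data.frame(
          subject_id = subj$subject_id, group = as.character(subj$group),
          condition = cond, run_index = r, seed = sn,
          stringsAsFactors = FALSE)
      }
    }
    resid_example <- fitted$residuals[seq_len(140), , drop = FALSE]
    rm(Y, fitted, runs)
  }
  list(z = do.call(rbind, zrows), meta = do.call(rbind, meta),
       resid_example = resid_example, ortho_max = ortho)
}
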