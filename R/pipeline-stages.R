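# Pipeline stage implementations behind run_pipeline(). Each stage writes
# its artifacts plus the shared config.json (hash-checked so artifacts from
# different configurations are never mixed).

stage_simulate <- function(config, out_dir) {
  check_hash(out_dir, config)
  log_msg("simulate: cohort ", config$n_ms, " MS / ", config$n_hc, " HC, grid ",
          paste(config$grid_dim, collapse = "x"))
  tables <- simulate_study_tables(config)
  write_config(config, file.path(out_dir, "config.json"))
  write_table_tsv(tables$cohort, file.path(out_dir, "cohort.tsv"))
  write_table_tsv(tables$vasf, file.path(out_dir, "vasf.tsv"))
  rf <- tables$run_fatigue
  attr(rf, "lambda") <- NULL
  write_table_tsv(rf, file.path(out_dir, "run_fatigue.tsv"))
  write_table_tsv(tables$behavior, file.path(out_dir, "behavior.tsv"))
  for (cond in names(tables$schedules)) {
    for (r in 1:4) {
      write_table_tsv(events_table(tables$schedules[[cond]][[r]]),
                      file.path(out_dir, sprintf("events_%s_run-%d.tsv",
                                                 gsub("-", "", cond), r)))
    }
  }
  # audit subject: one run's confounds table on disk
  grid <- study_grid(config$grid_dim)
  plant <- plant_from_config(config, grid)
  fat1 <- rf$fatigue_plant[rf$subject_id == tables$cohort$subject_id[1] &
                           rf$condition == "0-back" & rf$run_index == 1]
  run1 <- simulate_bold(tables$schedules[["0-back"]][[1]], fatigue = fat1,
                        plant = plant, grid = grid,
                        rng_seed = derive_seed(config$rng_seed, 10, 1, 1, 1))
  write_table_tsv(run1$confounds, file.path(out_dir, "confounds_sub-001_0back_run-1.tsv"))
  sidecar <- list(rng_seed = config$rng_seed, config_hash = config$config_hash,
                  n_vols = 140L, tr = grid$tr,
                  generated = c("cohort", "vasf", "run_fatigue", "behavior",
                                "events", "confounds(audit)"))
  jsonlite::write_json(sidecar, file.path(out_dir, "simulate_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("simulate: ", sum(rf$excluded), " zero-fatigue run(s) excluded")
  invisible(out_dir)
}

stage_first_level <- function(config, out_dir) {
  check_hash(out_dir, config)
  require_artifact(file.path(out_dir, "run_fatigue.tsv"), "simulate")
  tables <- simulate_study_tables(config)
  grid <- study_grid(config$grid_dim)
  plant <- plant_from_config(config, grid)
  rf <- tables$run_fatigue
  subj <- tables$cohort$subject_id[1]
  cond <- "0-back"
  runs <- lapply(1:4, function(r) {
    fat <- rf$fatigue_plant[rf$subject_id == subj & rf$condition == cond &
                            rf$run_index == r]
    simulate_bold(tables$schedules[[cond]][[r]], fatigue = fat, plant = plant,
                  grid = grid, rng_seed = derive_seed(config$rng_seed, 10, 1, 1, r))
  })
  Y <- do.call(rbind, lapply(runs, function(x) bold_matrix(x$bold)))
  design <- build_design(tables$schedules[[cond]],
                         lapply(runs, `[[`, "confounds"),
                         drift_order = config$drift_order, tr = grid$tr)
  fitted <- fit_glm(Y, design)
  ortho <- max(abs(crossprod(design$X, fitted$residuals))) / nrow(Y)
  log_msg("first-level: audit subject ", subj, ", max |X'resid|/n = ",
          format(ortho, digits = 3))
  res4d <- array(t(fitted$residuals), c(grid$dim, nrow(Y)))
  write_volume(res4d, file.path(out_dir, "residuals_sub-001_0back.nii.gz"),
               grid = grid)
  write_table_tsv(as.data.frame(design$X),
                  file.path(out_dir, "design_sub-001_0back.tsv"))
  jsonlite::write_json(list(config_hash = config$config_hash,
                            subject = subj, condition = cond,
                            max_abs_ortho = ortho),
                       file.path(out_dir, "first_level_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

stage_connectivity <- function(config, out_dir) {
  check_hash(out_dir, config)
  require_artifact(file.path(out_dir, "run_fatigue.tsv"), "simulate")
  tables <- simulate_study_tables(config)
  grid <- study_grid(config$grid_dim)
  plant <- plant_from_config(config, grid)
  seeds <- default_seeds()
  seed_voxels <- stats::setNames(lapply(seq_len(nrow(seeds)), function(i)
    voxelize_seed(c(seeds$x[i], seeds$y[i], seeds$z[i]), seeds$radius[i],
                  grid, seeds$name[i])), seeds$name)
  n_sub <- nrow(tables$cohort)
  zlist <- list(); mlist <- list(); resid_maps <- list(); ortho <- 0
  for (i in seq_len(n_sub)) {
    sm <- simulate_subject_maps(i, tables, config, grid, plant, seed_voxels)
    zlist[[i]] <- sm$z
    mlist[[i]] <- sm$meta
    ortho <- max(ortho, sm$ortho_max)
    if (i <= 6) resid_maps[[i]] <- array(sm$resid_example[1, ], grid$dim)
    log_msg("connectivity: subject ", i, "/", n_sub)
  }
  Z <- do.call(rbind, zlist)
  manifest <- do.call(rbind, mlist)
  manifest$map_index <- seq_len(nrow(manifest))
  for (sn in seeds$name) {
    rows <- which(manifest$seed == sn)
    arr <- array(t(Z[rows, , drop = FALSE]), c(grid$dim, length(rows)))
    write_volume(arr, file.path(out_dir, sprintf("zmaps_seed-%s.nii.gz", sn)),
                 grid = grid)
  }
  write_table_tsv(manifest, file.path(out_dir, "zmap_manifest.tsv"))
  sm_est <- estimate_smoothness(resid_maps, grid$voxel_mm)
  jsonlite::write_json(list(config_hash = config$config_hash,
                            max_abs_ortho = ortho,
                            resid_fwhm_mm = sm_est$fwhm_mean),
                       file.path(out_dir, "connectivity_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("connectivity: ", nrow(manifest), " maps; residual FWHM ~ ",
          format(sm_est$fwhm_mean, digits = 3), " mm")
  invisible(out_dir)
}

stage_behavior <- function(config, out_dir) {
  check_hash(out_dir, config)
  rf <- read_table_tsv(require_artifact(file.path(out_dir, "run_fatigue.tsv"),
                                        "simulate"))
  behav <- read_table_tsv(require_artifact(file.path(out_dir, "behavior.tsv"),
                                           "simulate"))
  keep <- !rf$excluded
  d <- rf[keep, ]
  fit_v <- fit_behavior_lme(d, response = "vasf", covariate = "run")
  behav2 <- merge(behav, rf[, c("subject_id", "condition", "run_index",
                                "transformed", "excluded")],
                  by = c("subject_id", "condition", "run_index"))
  behav2 <- behav2[!behav2$excluded, ]
  behav2$fatigue_t <- behav2$transformed
  fit_a <- fit_behavior_lme(behav2, response = "accuracy", covariate = "fatigue")
  fit_r <- fit_behavior_lme(behav2, response = "rt", covariate = "fatigue")
  cons <- pairwise_contrasts(fit_v, ~ condition | group)
  slopes <- pairwise_contrasts(fit_a, ~ group | condition, slopes = TRUE)
  out <- list(
    config_hash = config$config_hash,
    boxcox_lambda = if (length(unique(d$transformed)) > 1)
      boxcox_mle(d$run_mean)$lambda else NA,
    n_excluded_runs = sum(rf$excluded),
    vasf_fixed_effects = cbind(term = rownames(fit_v$coefficients),
                               fit_v$coefficients),
    accuracy_fixed_effects = cbind(term = rownames(fit_a$coefficients),
                                   fit_a$coefficients),
    rt_fixed_effects = cbind(term = rownames(fit_r$coefficients),
                             fit_r$coefficients))
  jsonlite::write_json(out, file.path(out_dir, "behavior_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_table_tsv(cons, file.path(out_dir, "vasf_condition_contrasts.tsv"))
  write_table_tsv(slopes, file.path(out_dir, "accuracy_slope_contrasts.tsv"))
  write_table_tsv(attr(slopes, "trends"),
                  file.path(out_dir, "accuracy_slopes_by_cell.tsv"))
  log_msg("behavior: ", sum(rf$excluded), " excluded runs; lambda = ",
          format(out$boxcox_lambda, digits = 3))
  invisible(out_dir)
}

stage_group <- function(config, out_dir) {
  check_hash(out_dir, config)
  manifest <- read_table_tsv(require_artifact(
    file.path(out_dir, "zmap_manifest.tsv"), "connectivity"))
  rf <- read_table_tsv(require_artifact(file.path(out_dir, "run_fatigue.tsv"),
                                        "simulate"))
  grid <- study_grid(config$grid_dim)
  rf$fatigue_c <- NA_real_
  for (g in unique(rf$group)) {
    sel <- rf$group == g & !rf$excluded
    rf$fatigue_c[sel] <- mean_center_by_group(rf$transformed[sel],
                                              rep(g, sum(sel)))
  }
  singular_total <- 0
  for (sn in unique(manifest$seed)) {
    vol <- read_volume(file.path(out_dir, sprintf("zmaps_seed-%s.nii.gz", sn)))
    Zs <- t(matrix(vol$data, prod(grid$dim)))
    man_s <- manifest[manifest$seed == sn, ]
    for (g in unique(man_s$group)) {
      rows <- which(man_s$group == g)
      meta <- man_s[rows, ]
      meta$key <- paste(meta$subject_id, meta$condition, meta$run_index)
      rf$key <- paste(rf$subject_id, rf$condition, rf$run_index)
      meta$fatigue_c <- rf$fatigue_c[match(meta$key, rf$key)]
      retained <- !is.na(meta$fatigue_c)
      sm <- voxelwise_fatigue_lme(Zs[rows[retained], , drop = FALSE],
                                  meta[retained, ])
      singular_total <- singular_total + sm$n_singular
      zmap <- contrast_sign_convention(sm)
      write_volume(array(sm$est, grid$dim),
                   file.path(out_dir, sprintf("group_est_seed-%s_%s.nii.gz", sn, g)),
                   grid = grid)
      write_volume(array(zmap, grid$dim),
                   file.path(out_dir, sprintf("group_z_seed-%s_%s.nii.gz", sn, g)),
                   grid = grid)
      write_volume(array(sm$p, grid$dim),
                   file.path(out_dir, sprintf("group_p_seed-%s_%s.nii.gz", sn, g)),
                   grid = grid)
      log_msg("group: seed ", sn, " group ", g, " (", sum(retained),
              " maps, ", sm$n_singular, " singular voxels)")
    }
  }
  jsonlite::write_json(list(config_hash = config$config_hash,
                            model = "z ~ condition * centered fatigue + run, random subject intercept",
                            n_excluded_runs = sum(rf$excluded),
                            singular_voxel_fits = singular_total),
                       file.path(out_dir, "group_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

stage_clusters <- function(config, out_dir) {
  check_hash(out_dir, config)
  sidecar <- require_artifact(file.path(out_dir, "connectivity_sidecar.json"),
                              "connectivity")
  fwhm <- jsonlite::fromJSON(sidecar)$resid_fwhm_mm
  manifest <- read_table_tsv(require_artifact(
    file.path(out_dir, "zmap_manifest.tsv"), "connectivity"))
  grid <- study_grid(config$grid_dim)
  mc <- montecarlo_extent_threshold(grid$dim, grid$voxel_mm, fwhm,
                                    voxel_p = config$voxel_p,
                                    alpha = config$alpha,
                                    n_sims = config$n_sims,
                                    connectivity = config$connectivity,
                                    rng_seed = derive_seed(config$rng_seed, 77))
  log_msg("clusters: extent threshold k = ", mc$k, " voxels at FWHM ",
          format(fwhm, digits = 3), " mm")
  jsonlite::write_json(list(config_hash = config$config_hash, k = mc$k,
                            fwhm_mm = fwhm, voxel_p = mc$voxel_p,
                            alpha = mc$alpha, n_sims = mc$n_sims,
                            connectivity = mc$connectivity,
                            calibration_fwe = mc$empirical_fwe),
                       file.path(out_dir, "cluster_threshold.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sn in unique(manifest$seed)) {
    for (g in unique(manifest$group)) {
      zfile <- require_artifact(
        file.path(out_dir, sprintf("group_z_seed-%s_%s.nii.gz", sn, g)), "group")
      zmap <- read_volume(zfile)$data
      tab <- cluster_table(zmap, grid, voxel_p = config$voxel_p,
                           extent_k = mc$k, connectivity = config$connectivity)
      write_table_tsv(tab, file.path(out_dir,
                      sprintf("clusters_seed-%s_%s.tsv", sn, g)))
    }
  }
  invisible(out_dir)
}
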