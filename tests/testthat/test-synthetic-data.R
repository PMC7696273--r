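test_that("cohort generation honors group counts, determinism and spread", {
  co <- generate_cohort(26, 14, rng_seed = 3)
  expect_equal(nrow(co), 40)
  expect_equal(sum(co$group == "MS"), 26)
  expect_equal(sum(co$group == "HC"), 14)
  expect_false(anyDuplicated(co$subject_id) > 0)
  expect_identical(co, generate_cohort(26, 14, rng_seed = 3))

  expect_equal(nrow(generate_cohort(0, 0, rng_seed = 1)), 0)
  expect_error(generate_cohort(-1, 5), "counts")

  big <- generate_cohort(1000, 1000, between_subject_sd = 0.5, rng_seed = 9)
  expect_lt(abs(sd(big$subject_intercept) - 0.5) / 0.5, 0.05)
})

test_that("task schedules have 65 trials, 260 s budget, and conserve time", {
  for (seed in c(1, 22, 303)) {
    s <- generate_task_schedule("0-back", 1, rng_seed = seed)
    expect_length(s$onsets, 65)
    expect_equal(s$run_length, 260)
    expect_true(all(diff(s$onsets) > 0))
    expect_true(all(s$durations == 1.5))
    # brute-force accumulation over the emitted timeline: trial slots plus
    # null events must fill the run exactly
    total <- 65 * (1.5 + 0.5) + sum(s$null_durations)
    expect_equal(total, 260)
    expect_equal(max(s$onsets) + 1.5 + 0.5 +
                   sum(s$null_durations[s$null_after_trial == 65]), 260)
    # null durations are positive multiples of the 2-s trial length
    expect_length(s$null_durations, 6)
    expect_true(all(s$null_durations %% 2 == 0 & s$null_durations > 0))
  }
  expect_identical(generate_task_schedule("2-back", 2, rng_seed = 5),
                   generate_task_schedule("2-back", 2, rng_seed = 5))
})

test_that("zero-null schedule variant is strictly periodic; bad budgets error", {
  s <- generate_task_schedule("0-back", 1, rng_seed = 1, n_null = 0,
                              run_length = 130)
  expect_equal(s$onsets, seq(0, by = 2, length.out = 65))
  expect_error(generate_task_schedule("0-back", 1, n_null = 0),
               "impossible timing budget")
  expect_error(generate_task_schedule("0-back", 1, run_length = 131),
               "impossible timing budget")
  expect_error(generate_task_schedule("0-back", 1, run_length = 132,
                                      n_null = 6),
               "impossible timing budget")
})

test_that("fatigue ratings: 5 per subject x condition, clipping, group effect", {
  co <- generate_cohort(3, 2, rng_seed = 1)
  v <- generate_vasf(co, rng_seed = 2)
  counts <- table(v$subject_id, v$condition)
  expect_true(all(counts == 5))
  expect_true(all(v$score >= 0 & v$score <= 100))

  # deterministic constant case
  p0 <- vasf_params(baseline = 30, ms_offset = 0, cond_offset_2back = 0,
                    rating_trend = 0, subject_scale = 0, noise_sd = 0)
  v0 <- generate_vasf(co, p0, rng_seed = 1)
  expect_true(all(v0$score == 30))

  # zero baseline: exclusion fodder downstream
  pz <- vasf_params(baseline = 0, ms_offset = 0, cond_offset_2back = 0,
                    rating_trend = 0, subject_scale = 0, noise_sd = 0)
  expect_true(all(generate_vasf(co, pz, rng_seed = 1)$score == 0))

  big <- generate_cohort(150, 150, rng_seed = 7)
  vb <- generate_vasf(big, rng_seed = 8)
  expect_gt(median(vb$score[vb$group == "MS"]),
            median(vb$score[vb$group == "HC"]))
})

test_that("behavioral generator respects ranges and planted slope pattern", {
  co <- generate_cohort(120, 120, rng_seed = 11)
  v <- generate_vasf(co, rng_seed = 12)
  rf <- compute_run_fatigue(v)
  b <- generate_behavior(co, rf, rng_seed = 13)
  expect_equal(nrow(b), nrow(rf))
  expect_true(all(b$accuracy >= 0 & b$accuracy <= 1))
  expect_true(all(b$mean_rt > 0))
  # 2-back slower than 0-back on average (planted RT cost)
  expect_gt(mean(b$mean_rt[b$condition == "2-back"]),
            mean(b$mean_rt[b$condition == "0-back"]))
})

test_that("simulated runs have 140 volumes and a bit-reproducible stream", {
  g <- make_test_grid(c(6L, 6L, 6L))
  s <- generate_task_schedule("0-back", 1, rng_seed = 4)
  p <- plant_spec(task_region = 1:10, noise_sd = 0.3, smoothing_fwhm = 0)
  r1 <- simulate_bold(s, 0, p, g, rng_seed = 9)
  expect_equal(dim(r1$bold$data), c(6, 6, 6, 140))
  expect_equal(nrow(r1$confounds), 140)
  r2 <- simulate_bold(s, 0, p, g, rng_seed = 9)
  expect_identical(r1$bold$data, r2$bold$data)
  expect_identical(r1$confounds, r2$confounds)
  expect_error(simulate_bold(s, 0, plant_spec(task_region = 1:1000), g),
               "outside the grid")
})

test_that("fully modeled signal leaves numerically zero residuals", {
  # no noise, no coupling, no drift: task + motion + tissue fluctuations are
  # all in the design span, so the deconvolution must absorb everything
  g <- make_test_grid(c(6L, 6L, 6L))
  p <- plant_spec(task_region = 30:60, noise_sd = 0, latent_sd = 0,
                  drift_coeffs = numeric(0), smoothing_fwhm = 0)
  sch <- test_schedules("0-back")
  runs <- lapply(1:4, function(r)
    simulate_bold(sch[[r]], 0, p, g, rng_seed = 40 + r))
  Y <- do.call(rbind, lapply(runs, function(x) {
    d <- dim(x$bold$data); t(matrix(x$bold$data, prod(d[1:3]), d[4]))
  }))
  fit <- fit_glm(Y, build_design(sch, lapply(runs, `[[`, "confounds"),
                                 drift_order = 1))
  expect_lt(max(abs(fit$residuals)) / max(abs(Y)), 1e-8)
})

test_that("planted seed-target coupling tracks fatigue across runs", {
  g <- make_test_grid(c(8L, 8L, 8L))
  seed_reg <- 1:8
  targ_reg <- 400:420
  p <- plant_spec(seed_region = seed_reg, target_region = targ_reg,
                  coupling_intercept = 0, coupling_slope_2back = 0.4,
                  noise_sd = 0)
  fats <- c(-1, 0, 1, 2)
  cors <- vapply(seq_along(fats), function(i) {
    s <- generate_task_schedule("2-back", 1, rng_seed = i)
    r <- simulate_bold(s, fats[i], p, g, rng_seed = 100 + i)
    cor(r$truth$latent_seed, r$truth$latent_target)
  }, numeric(1))
  planted <- tanh(0.4 * fats)
  expect_true(all(diff(cors) > 0))
  # per-run sample correlation close to plant (n = 140 volumes)
  expect_true(all(abs(cors - planted) < 0.2))
})

test_that("planted correlations stay inside (-1, 1) and refuse non-finite", {
  p <- plant_spec(coupling_intercept = 5, coupling_slope_2back = 10)
  expect_lt(abs(resifc:::planted_correlation(p, "2-back", 50)), 1)
  expect_error(resifc:::planted_correlation(p, "2-back", Inf), "not finite")
})
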