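test_that("seed voxelization matches exhaustive distance enumeration", {
  g <- make_test_grid(c(8L, 8L, 8L), voxel = 3, origin = c(0, 0, 0))
  # radius 0 on a voxel centre: exactly that voxel
  c1 <- drop(voxel_to_mm(g, c(4, 4, 4)))
  expect_length(voxelize_seed(c1, 0, g), 1)
  # 4 mm on a 3 mm grid, centre on a voxel centre: centre + 6 faces = 7
  v7 <- voxelize_seed(c1, 4, g)
  expect_length(v7, 7)
  expect_identical(v7, enumerate_seed_voxels(c1, 4, g))
  # off-centre and larger radii against the exhaustive oracle
  for (r in c(2.9, 4, 5.5)) {
    ctr <- c1 + c(1.2, -0.7, 0.4)
    expect_identical(voxelize_seed(ctr, r, g), enumerate_seed_voxels(ctr, r, g))
  }
  expect_error(voxelize_seed(c(1000, 0, 0), 4, g), "outside the grid")
})

test_that("default seeds match the study coordinates and fit the default grid", {
  seeds <- default_seeds()
  dl <- seeds[seeds$name == "DLPFC", ]
  expect_equal(c(dl$x, dl$y, dl$z), c(44, 32, 36))
  expect_equal(seeds$radius, rep(4, 5))
  g <- fc_grid()
  for (i in seq_len(nrow(seeds)))
    expect_gt(length(voxelize_seed(c(seeds$x[i], seeds$y[i], seeds$z[i]),
                                   seeds$radius[i], g, seeds$name[i])), 0)
})

test_that("seed mean PSC series reduces correctly", {
  set.seed(3)
  raw <- matrix(rnorm(40 * 10, 100, 1), 40)
  resid <- matrix(rnorm(40 * 10), 40)

  # single-voxel seed equals that voxel's PSC residual series
  expect_equal(seed_series(resid, raw, 4),
               100 * resid[, 4] / mean(raw[, 4]))

  # two voxels with series s and -s (equal raw means): all-zero seed series
  raw2 <- cbind(rep(100, 40), rep(100, 40))
  s <- rnorm(40)
  expect_equal(seed_series(cbind(s, -s), raw2, 1:2), rep(0, 40))

  # random fixture against a loop-based oracle
  idx <- c(2, 5, 9)
  ref <- colMeans(raw[, idx])
  psc <- sapply(seq_along(idx), function(j) 100 * resid[, idx[j]] / ref[j])
  expect_equal(seed_series(resid, raw, idx), loop_mask_mean(psc, 1:3))
  expect_error(seed_series(resid, raw, integer(0)), "empty seed")
})

test_that("Fisher-z maps behave as the transform dictates", {
  set.seed(5)
  n <- 200
  seed_ts <- rnorm(n)
  # perfect correlation hits the clamp ceiling
  z <- connectivity_zmap(seed_ts, cbind(seed_ts, -seed_ts))
  expect_equal(z[1], atanh(1 - 1e-7))
  expect_equal(z[2], -atanh(1 - 1e-7))

  # closed form at r = 0.5 (construct exact correlation)
  a <- scale(rnorm(n))[, 1]
  b <- scale(residuals(lm(rnorm(n) ~ a)))[, 1]
  y <- 0.5 * a + sqrt(0.75) * b
  expect_equal(connectivity_zmap(a, cbind(y)), atanh(0.5), tolerance = 1e-6)

  # independent white noise: |z| below 3 / sqrt(n - 3)
  noise <- matrix(rnorm(n * 50), n)
  zn <- connectivity_zmap(seed_ts, noise)
  expect_lt(max(abs(zn)), 3 / sqrt(n - 3) * 1.6)
  expect_gt(mean(abs(zn) < 3 / sqrt(n - 3)), 0.95)

  # antisymmetry and scale invariance
  expect_equal(connectivity_zmap(-seed_ts, noise), -zn)
  expect_equal(connectivity_zmap(seed_ts, noise * 7 + 3), zn)

  expect_error(connectivity_zmap(rep(1, n), noise), "zero variance")
  expect_warning(z0 <- connectivity_zmap(seed_ts, cbind(rep(2, n))),
                 "zero-variance")
  expect_equal(unname(z0), 0)
})

test_that("target-region z rises with the planted fatigue weight across runs", {
  g <- make_test_grid(c(8L, 8L, 8L))
  seed_reg <- voxelize_seed(drop(voxel_to_mm(g, c(2, 4, 4))), 4, g)
  targ_reg <- voxelize_seed(drop(voxel_to_mm(g, c(7, 4, 4))), 4, g)
  p <- plant_spec(seed_region = seed_reg, target_region = targ_reg,
                  coupling_intercept = 0, coupling_slope_2back = 0.5,
                  noise_sd = 0.3, smoothing_fwhm = 3)
  fats <- c(-1.5, -0.5, 0.5, 1.5)
  sch <- test_schedules("2-back")
  mean_z <- vapply(seq_along(fats), function(i) {
    runs <- lapply(1:4, function(r)
      simulate_bold(sch[[r]], fats[i], p, g, rng_seed = 500 + 10 * i + r))
    Y <- do.call(rbind, lapply(runs, function(x) {
      d <- dim(x$bold$data); t(matrix(x$bold$data, prod(d[1:3]), d[4]))
    }))
    fit <- fit_glm(Y, build_design(sch, lapply(runs, `[[`, "confounds"),
                                   drift_order = 1))
    zs <- vapply(1:4, function(r) {
      rows <- (r - 1) * 140 + 1:140
      ts <- seed_series(fit$residuals[rows, ], Y[rows, ], seed_reg)
      mean(connectivity_zmap(ts, fit$residuals[rows, ])[targ_reg])
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_gt(cor(mean_z, fats, method = "spearman"), 0)
  expect_true(all(diff(mean_z) > 0))
})
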