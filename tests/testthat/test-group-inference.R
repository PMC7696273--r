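# Helper: build a synthetic stack of per-run Fisher-z "maps" directly
# (no imaging), with a known condition-by-fatigue interaction in some voxels.
make_z_stack <- function(n_sub = 12, n_vox = 60, slope2 = 0, slope0 = 0,
                         target = integer(0), subj_sd = 0.3, noise_sd = 0.2,
                         seed = 1) {
  set.seed(seed)
  meta <- expand.grid(run_index = 1:4, condition = c("0-back", "2-back"),
                      subject_id = sprintf("s%02d", 1:n_sub),
                      stringsAsFactors = FALSE)
  meta$fatigue_c <- rnorm(nrow(meta))
  meta$fatigue_c <- meta$fatigue_c - mean(meta$fatigue_c)
  subj_eff <- rnorm(n_sub, 0, subj_sd)
  Z <- matrix(rnorm(nrow(meta) * n_vox, 0, noise_sd), nrow(meta))
  Z <- Z + subj_eff[as.integer(factor(meta$subject_id))]
  sl <- ifelse(meta$condition == "2-back", slope2, slope0)
  Z[, target] <- Z[, target] + sl * meta$fatigue_c
  list(Z = Z, meta = meta)
}

test_that("group-wise mean centering is exact and idempotent", {
  expect_equal(mean_center_by_group(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  v <- rnorm(30); g <- rep(c("MS", "HC"), 15)
  c1 <- mean_center_by_group(v, g)
  expect_lt(abs(sum(c1[g == "MS"])), 1e-10)
  expect_lt(abs(sum(c1[g == "HC"])), 1e-10)
  expect_equal(mean_center_by_group(c1, g), c1)
  expect_error(mean_center_by_group(numeric(0), factor(levels = "a")), "empty")
})

test_that("identical condition maps give a null interaction map", {
  st <- make_z_stack(n_sub = 8, n_vox = 20, seed = 2)
  # make the two conditions carry identical maps per subject x run
  key0 <- with(st$meta, paste(subject_id, run_index))
  for (k in unique(key0)) {
    rows <- which(key0 == k)
    st$Z[rows[st$meta$condition[rows] == "2-back"], ] <-
      st$Z[rows[st$meta$condition[rows] == "0-back"], ]
  }
  # identical maps AND identical covariate within pair -> exact symmetry
  st$meta$fatigue_c <- ave(st$meta$fatigue_c, key0)
  sm <- voxelwise_fatigue_lme(st$Z, st$meta)
  expect_lt(max(abs(sm$est)), 1e-10)
})

test_that("relabeling conditions flips the interaction sign exactly", {
  st <- make_z_stack(n_sub = 10, n_vox = 30, slope2 = 0.3,
                     target = 1:5, seed = 3)
  sm1 <- voxelwise_fatigue_lme(st$Z, st$meta)
  meta_flip <- st$meta
  meta_flip$condition <- ifelse(meta_flip$condition == "2-back",
                                "0-back", "2-back")
  sm2 <- voxelwise_fatigue_lme(st$Z, meta_flip)
  expect_equal(sm2$est, -sm1$est, tolerance = 1e-10)
  expect_equal(sm2$p, sm1$p, tolerance = 1e-9)
})

test_that("planted interaction slope is recovered with correct sign map", {
  st <- make_z_stack(n_sub = 14, n_vox = 50, slope2 = 0.25, slope0 = 0,
                     target = 1:8, seed = 4)
  sm <- voxelwise_fatigue_lme(st$Z, st$meta)
  expect_lt(max(abs(mean(sm$est[1:8]) - 0.25)),
            3 * mean(sm$se[1:8]) / sqrt(8) + 0.02)
  expect_true(all(sm$p[1:8] < 0.001))
  expect_gt(min(abs(sm$tstat[1:8])), max(abs(sm$tstat[9:50])))

  # signed Z convention: monotone in t, round-trips the p-value
  z <- contrast_sign_convention(sm)
  expect_true(all(sign(z) == sign(sm$tstat)))
  expect_equal(2 * pnorm(-abs(z)), sm$p, tolerance = 1e-6)
  ord <- order(sm$tstat)
  expect_true(all(diff(z[ord]) >= 0))

  # stratified parameterization estimates the same slope difference
  sm_str <- voxelwise_fatigue_lme(st$Z, st$meta, stratified = TRUE)
  expect_equal(sm_str$est, sm$est, tolerance = 1e-8)
})

test_that("subject-constant offsets are absorbed by the random intercept", {
  st <- make_z_stack(n_sub = 8, n_vox = 15, slope2 = 0.2, target = 1:3,
                     seed = 5)
  sm1 <- voxelwise_fatigue_lme(st$Z, st$meta)
  offs <- seq(0.5, 4, length.out = 8)
  Z2 <- st$Z + offs[as.integer(factor(st$meta$subject_id))]
  sm2 <- voxelwise_fatigue_lme(Z2, st$meta)
  # offsets land in the random-intercept variance, and the interaction map
  # moves only through the re-estimated variance ratio (under one SE)
  expect_lt(max(abs(sm2$est - sm1$est) / sm1$se), 1)
  expect_gt(mean(sm2$sigma2_b), 10 * mean(sm1$sigma2_b))
  expect_equal(sign(sm2$tstat[1:3]), sign(sm1$tstat[1:3]))
})

test_that("voxelwise test keeps its nominal false-positive rate under the null", {
  n_hits <- 0; n_tests <- 0
  for (s in 1:50) {
    st <- make_z_stack(n_sub = 10, n_vox = 40, seed = 100 + s)
    sm <- voxelwise_fatigue_lme(st$Z, st$meta)
    n_hits <- n_hits + sum(sm$p < 0.001)
    n_tests <- n_tests + length(sm$p)
  }
  expect_lte(n_hits / n_tests, 0.002)
})

test_that("group model validates inputs and run coding options", {
  st <- make_z_stack(n_sub = 6, n_vox = 10, seed = 6)
  expect_error(voxelwise_fatigue_lme(st$Z, st$meta[, 1:2]), "meta must contain")
  one <- st$meta$subject_id == "s01"
  expect_error(voxelwise_fatigue_lme(st$Z[one, ], st$meta[one, ]),
               "at least 2 subjects")
  sm_num <- voxelwise_fatigue_lme(st$Z, st$meta, run_as = "numeric")
  expect_length(sm_num$est, 10)
})
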