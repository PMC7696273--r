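test_that("cluster labeling equals brute-force flood fill on small grids", {
  set.seed(17)
  rules <- c("faces", "faces+edges", "faces+edges+corners")
  for (n in c(2L, 4L, 6L, 8L)) {
    for (fill in c(0.15, 0.4, 0.7)) {
      mask <- array(runif(n^3) < fill, c(n, n, n))
      for (rule in rules) {
        ours <- resifc:::label_components(mask, rule)
        oracle <- flood_fill_components(mask, resifc:::neighbor_offsets(rule))
        expect_identical(canonical_labels(ours$labels),
                         canonical_labels(oracle))
        expect_setequal(as.integer(table(oracle[oracle > 0])), ours$sizes)
      }
    }
  }
})

test_that("hand-built shapes label as enumerated", {
  # L-shaped 5-voxel blob: one cluster under the faces rule
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2:4, 2] <- TRUE
  m[3:4, 4, 2] <- TRUE
  lab <- label_clusters(m, connectivity = "faces")
  expect_equal(nrow(lab$clusters), 1)
  expect_equal(lab$clusters$size, 5)

  # two diagonally touching voxels: 2 clusters under faces, 1 under corners
  d <- array(FALSE, c(3, 3, 3))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(nrow(label_clusters(d, connectivity = "faces")$clusters), 2)
  expect_equal(nrow(label_clusters(d,
    connectivity = "faces+edges+corners")$clusters), 1)

  # empty map: no clusters
  e <- label_clusters(array(FALSE, c(4, 4, 4)))
  expect_equal(nrow(e$clusters), 0)

  # signed map: positive and negative sides labeled separately
  z <- array(0, c(4, 4, 4))
  z[1:2, 1, 1] <- 5
  z[4, 4, 3:4] <- -4
  cl <- label_clusters(z, threshold = 3)$clusters
  expect_equal(sort(cl$sign), c(-1, 1))
  expect_equal(cl$peak_value[cl$sign == 1], 5)
})

test_that("smoothness estimator hits its white-noise value and recovers 6 mm", {
  set.seed(23)
  maps <- lapply(1:6, function(i) array(rnorm(20^3), c(20, 20, 20)))
  sm <- estimate_smoothness(maps, voxel_mm = 3)
  # spatially independent noise: estimator value is voxel * sqrt(2 log 2)
  expect_lt(abs(sm$fwhm_mean - 3 * sqrt(2 * log(2))) / (3 * sqrt(2 * log(2))),
            0.10)

  maps6 <- lapply(1:6, function(i)
    resifc:::simulate_null_field(c(20, 20, 20), 3, 6))
  sm6 <- estimate_smoothness(maps6, voxel_mm = 3)
  expect_lt(abs(sm6$fwhm_mean - 6) / 6, 0.15)

  # invariant to global rescaling
  sm6b <- estimate_smoothness(lapply(maps6, function(m) 13 * m), voxel_mm = 3)
  expect_equal(sm6b$fwhm, sm6$fwhm)

  expect_error(estimate_smoothness(list(array(1, c(4, 4, 4)),
                                        array(1, c(4, 4, 4))), 3), "constant")
  expect_error(estimate_smoothness(list(maps[[1]]), 3), "at least 2")
})

test_that("Monte-Carlo extent calibration behaves at its edges", {
  # voxel_p so small nothing survives: k = 1, empirical FWE 0
  mc0 <- montecarlo_extent_threshold(c(8, 8, 8), 3, 0, voxel_p = 1e-12,
                                     n_sims = 200, rng_seed = 5)
  expect_equal(mc0$k, 1L)
  expect_equal(mc0$empirical_fwe, 0)

  # FWHM 0 (independent voxels): P(any suprathreshold voxel) matches the
  # binomial closed form
  p <- 0.01; dims <- c(10, 10, 10)
  mc1 <- montecarlo_extent_threshold(dims, 3, 0, voxel_p = p, n_sims = 400,
                                     rng_seed = 6)
  p_any <- mean(mc1$max_extents >= 1)
  closed <- 1 - (1 - p)^prod(dims)
  expect_lt(abs(p_any - closed), 3 * sqrt(closed * (1 - closed) / 400) + 0.02)

  # k non-increasing in alpha over the same null sample
  ks <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    resifc:::smallest_calibrated_extent(mc1$max_extents, a), integer(1))
  expect_true(all(diff(ks) <= 0))

  expect_error(montecarlo_extent_threshold(c(8, 8, 8), 3, 6, voxel_p = 2),
               "voxel_p")
  expect_error(montecarlo_extent_threshold(c(8, 8, 8), 3, 6, n_sims = 10),
               "n_sims")
})

test_that("cluster tables report planted blobs in mm with the extent filter", {
  g <- make_test_grid(c(10L, 10L, 10L), voxel = 3, origin = c(-12, -12, -12))
  z <- array(0, c(10, 10, 10))
  z[4:6, 5:7, 5] <- 4.5
  z[5, 6, 5] <- 6          # peak
  z[9, 9, 9] <- 5          # isolated single voxel
  tab <- cluster_table(z, g, voxel_p = 0.001, extent_k = 3)
  expect_equal(nrow(tab), 1)  # singleton filtered by extent
  expect_true(all(tab$voxels >= 3))
  expect_equal(c(tab$x, tab$y, tab$z),
               drop(voxel_to_mm(g, c(5, 6, 5))), tolerance = 1e-9)
  expect_equal(tab$peak_z, 6)

  # empty result
  expect_equal(nrow(cluster_table(array(0, c(10, 10, 10)), g, extent_k = 1)), 0)

  # negative clusters carry their sign; ordering is positive first
  z[2, 2, 8:9] <- -7
  tab2 <- cluster_table(z, g, voxel_p = 0.001, extent_k = 2)
  expect_equal(tab2$sign, c(1, -1))
  expect_equal(tab2$peak_z[2], -7)
  expect_error(cluster_table(z, g, extent_k = 0), "extent_k")
})

test_that("doubling the null sample hardly moves the calibrated extent", {
  mc_a <- montecarlo_extent_threshold(c(12, 12, 12), 3, 6, n_sims = 400,
                                      rng_seed = 9)
  mc_b <- montecarlo_extent_threshold(c(12, 12, 12), 3, 6, n_sims = 800,
                                      rng_seed = 10)
  expect_lte(abs(mc_a$k - mc_b$k), 1)
})
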