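# Independent oracles used across tests. These deliberately use naive
# algorithms (recursion, exhaustive enumeration, elementwise loops) so they
# share no code with the implementation they check.

# Brute-force connected components by repeated flood fill.
flood_fill_components <- function(mask, offsets) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (lin in which(mask)) {
    if (lab[lin] != 0L) next
    cur <- cur + 1L
    queue <- lin
    lab[lin] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vc <- arrayInd(v, d)
      for (r in seq_len(nrow(offsets))) {
        nb <- vc + offsets[r, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[nl] && lab[nl] == 0L) {
          lab[nl] <- cur
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

# Normalize a labeling to a canonical form so two labelings can be compared
# regardless of label numbering.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab != 0])
  out <- array(0L, dim(lab))
  first_seen <- ids[order(vapply(ids, function(g) min(which(lab == g)),
                                 numeric(1)))]
  for (i in seq_along(first_seen)) out[lab == first_seen[i]] <- i
  out
}

# Loop-based per-volume mean over a voxel set.
loop_mask_mean <- function(mat, idx) {
  out <- numeric(nrow(mat))
  for (t in seq_len(nrow(mat))) {
    s <- 0
    for (v in idx) s <- s + mat[t, v]
    out[t] <- s / length(idx)
  }
  out
}

# Exhaustive seed voxelization: test every voxel centre's distance.
enumerate_seed_voxels <- function(center_mm, radius, grid) {
  hits <- integer(0)
  lin <- 0L
  for (k in seq_len(grid$dim[3])) for (j in seq_len(grid$dim[2]))
    for (i in seq_len(grid$dim[1])) {
      mm <- drop(resifc::voxel_to_mm(grid, c(i, j, k)))
      l <- i + (j - 1L) * grid$dim[1] + (k - 1L) * grid$dim[1] * grid$dim[2]
      if (sqrt(sum((mm - center_mm)^2)) <= radius + 1e-9) hits <- c(hits, l)
    }
  sort(hits)
}

make_test_grid <- function(dim = c(8L, 8L, 8L), voxel = 3, origin = c(0, 0, 0)) {
  resifc::fc_grid(dim = dim, voxel_mm = voxel, origin_mm = origin)
}

# Small standard schedule list (one per run) reused in GLM tests.
test_schedules <- function(condition = "0-back", seed = 7) {
  lapply(1:4, function(r)
    resifc::generate_task_schedule(condition, r, rng_seed = seed + r))
}

# Simulated confounds for design-building tests.
test_confounds <- function(n_vols = 140, seed = 5) {
  lapply(1:4, function(r) {
    motion <- resifc::simulate_motion(n_vols, rng_seed = seed + r)
    sig <- matrix(stats::rnorm(n_vols * 30, 1000, 2), n_vols)
    fd <- resifc::framewise_displacement(motion)
    dv <- resifc::standardized_dvars(sig, seq_len(30))
    tis <- resifc::tissue_mean_signals(sig, 1:5, 6:10, 1:30)
    resifc::expand_confounds(motion, fd, dv, tis)
  })
}
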