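#' Neighborhood offsets for 3-D connectivity rules
#'
#' `"faces"` (6 neighbors, NN1), `"faces+edges"` (18, NN2),
#' `"faces+edges+corners"` (26, NN3).
#' @param connectivity Connectivity rule name.
#' @return Integer matrix, one offset per row.
#' @keywords internal
neighbor_offsets <- function(connectivity = c("faces", "faces+edges",
                                              "faces+edges+corners")) {
  connectivity <- match.arg(connectivity)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(off != 0) > 0, ]
  keep <- switch(connectivity,
                 "faces" = rowSums(abs(off)) == 1,
                 "faces+edges" = rowSums(abs(off)) <= 2,
                 "faces+edges+corners" = rep(TRUE, nrow(off)))
  off[keep, , drop = FALSE]
}

# Connected components of a logical 3-D mask; returns an integer label
# array (0 = background) and component sizes.
label_components <- function(mask, connectivity = "faces") {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L)
    return(list(labels = lab, sizes = integer(0)))
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  off <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- rank[nb_lin] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, rank[nb_lin[hit]])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership[seq_along(idx)]
  list(labels = lab, sizes = as.integer(comp$csize))
}

#' Label suprathreshold clusters of a signed statistic map
#'
#' Positive and negative suprathreshold voxels are labeled separately
#' (two-sided convention); each cluster's peak is its voxel of maximum
#' absolute value, ties broken by smallest linear index.
#'
#' @param map Numeric 3-D array (signed statistic) or logical mask.
#' @param threshold Suprathreshold cut: voxels with `map >= threshold`
#'   (positive side) or `map <= -threshold` (negative side). Ignored for a
#'   logical map, which is labeled as a single positive set.
#' @param connectivity See [neighbor_offsets()].
#' @return List with `clusters` (data.frame: `cluster_id`, `sign`, `size`,
#'   `peak_i/j/k`, `peak_value`) and `labels` (signed integer array;
#'   negative labels for negative clusters).
#' @export
label_clusters <- function(map, threshold = NULL,
                           connectivity = c("faces", "faces+edges",
                                            "faces+edges+corners")) {
  connectivity <- match.arg(connectivity)
  if (is.logical(map)) {
    masks <- list(pos = map, neg = array(FALSE, dim(map)))
    vals <- array(as.numeric(map), dim(map))
  } else {
    if (is.null(threshold)) abort_arg("numeric map needs a threshold")
    masks <- list(pos = map >= threshold, neg = map <= -threshold)
    vals <- map
  }
  d <- dim(vals)
  labels <- array(0L, d)
  rows <- list()
  for (sgn in c(1, -1)) {
    m <- if (sgn > 0) masks$pos else masks$neg
    comp <- label_components(m, connectivity)
    if (length(comp$sizes) == 0) next
    labels <- labels + sgn * comp$labels
    for (cid in seq_along(comp$sizes)) {
      vox <- which(comp$labels == cid)
      pk <- vox[which.max(abs(vals[vox]))]   # which.max takes first on ties
      pc <- arrayInd(pk, d)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = sgn * cid, sign = sgn, size = comp$sizes[cid],
        peak_i = pc[1], peak_j = pc[2], peak_k = pc[3],
        peak_value = vals[pk])
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
              else data.frame(cluster_id = integer(0), sign = integer(0),
                              size = integer(0), peak_i = integer(0),
                              peak_j = integer(0), peak_k = integer(0),
                              peak_value = numeric(0))
  list(clusters = clusters, labels = labels)
}

#' Spatial smoothness (FWHM) of residual maps
#'
#' Gaussian-field estimator from the variance of spatial first differences
#' of standardized maps: along each axis,
#' `FWHM = voxel * sqrt(4 log(2) * var / var_diff)`, averaged over maps.
#' Under spatially independent noise the estimator's value is
#' `voxel * sqrt(2 log 2)` (about 1.18 voxels); smoother fields give larger
#' values.
#'
#' @param maps List of 3-D arrays (or a single array), e.g. per-subject
#'   residual or z maps. At least 2 maps; constant maps are an error.
#' @param voxel_mm Voxel edge length (mm).
#' @return List of class `fc_smoothness`: `fwhm` (per-axis, mm) and
#'   `fwhm_mean`.
#' @export
estimate_smoothness <- function(maps, voxel_mm) {
  if (is.array(maps) && length(dim(maps)) == 3L) maps <- list(maps)
  if (length(maps) < 2L) abort_arg("need at least 2 maps")
  per_map <- sapply(maps, function(m) {
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) abort_arg("constant map: smoothness undefined")
    m <- (m - mean(m)) / s
    vapply(1:3, function(ax) {
      dm <- apply(m, setdiff(1:3, ax), diff)
      vd <- stats::var(as.vector(dm))
      voxel_mm * sqrt(4 * log(2) / vd)
    }, numeric(1))
  })
  fwhm <- rowMeans(per_map)
  structure(list(fwhm = fwhm, fwhm_mean = mean(fwhm),
                 method = "first-difference Gaussian-field estimator"),
            class = "fc_smoothness")
}

#' Monte-Carlo cluster-extent threshold calibration
#'
#' Simulates null Gaussian random fields at the stated smoothness
#' (white noise smoothed with a Gaussian kernel, then standardized exactly
#' to unit voxel variance), thresholds two-sided at `voxel_p`, labels
#' positive and negative clusters separately, and records the maximum
#' cluster extent per simulation. The extent threshold `k` is the smallest
#' integer with empirical `P(max extent >= k) <= alpha`.
#'
#' @param dim Grid dimensions (3 integers).
#' @param voxel_mm Voxel size (mm).
#' @param fwhm Field smoothness (mm).
#' @param voxel_p Two-sided voxelwise probability threshold.
#' @param alpha Desired familywise error level.
#' @param n_sims Number of null simulations (>= 200).
#' @param connectivity See [neighbor_offsets()].
#' @param rng_seed Integer seed; the null distribution is a pure function
#'   of it.
#' @return Object of class `fc_mcnull`: `k`, sorted `max_extents`,
#'   `empirical_fwe` (at `k`, on the calibration sample), and parameters.
#' @export
montecarlo_extent_threshold <- function(dim, voxel_mm, fwhm,
                                        voxel_p = 0.001, alpha = 0.05,
                                        n_sims = 1000,
                                        connectivity = c("faces", "faces+edges",
                                                         "faces+edges+corners"),
                                        rng_seed = NULL) {
  connectivity <- match.arg(connectivity)
  if (voxel_p <= 0 || voxel_p >= 1) abort_arg("voxel_p must be in (0,1)")
  if (alpha <= 0 || alpha >= 1) abort_arg("alpha must be in (0,1)")
  if (n_sims < 200) abort_arg("n_sims must be >= 200")
  zc <- stats::qnorm(1 - voxel_p / 2)
  samples <- with_rng_seed(rng_seed, {
    vapply(seq_len(n_sims), function(s) {
      max_null_cluster_extent(dim, voxel_mm, fwhm, zc, connectivity)
    }, numeric(1))
  })
  k <- smallest_calibrated_extent(samples, alpha)
  structure(list(k = k, max_extents = sort(samples),
                 empirical_fwe = mean(samples >= k),
                 n_sims = n_sims, voxel_p = voxel_p, alpha = alpha,
                 fwhm = fwhm, dim = dim, voxel_mm = voxel_mm,
                 connectivity = connectivity),
            class = "fc_mcnull")
}

#' @export
print.fc_mcnull <- function(x, ...) {
  cat(sprintf(
    "<fc_mcnull> k = %d voxels (voxel p %g, alpha %g, FWHM %g mm, %d sims); calibration FWE %.4f\n",
    x$k, x$voxel_p, x$alpha, x$fwhm, x$n_sims, x$empirical_fwe))
  invisible(x)
}

# One null field's maximum suprathreshold cluster extent.
max_null_cluster_extent <- function(dim, voxel_mm, fwhm, zcrit, connectivity) {
  z <- simulate_null_field(dim, voxel_mm, fwhm)
  supra <- abs(z) > zcrit
  if (!any(supra)) return(0)
  sz <- c(label_components(z > zcrit & supra, connectivity)$sizes,
          label_components(z < -zcrit, connectivity)$sizes)
  if (length(sz) == 0) 0 else max(sz)
}

# Unit-variance Gaussian null field at the given smoothness. The exact
# per-voxel sd of the smoothed field is divided out, so edge voxels are
# standardized correctly too.
simulate_null_field <- function(dim, voxel_mm, fwhm) {
  e <- array(stats::rnorm(prod(dim)), dim)
  if (fwhm <= 0) return(e)
  s <- smooth_gaussian(e, fwhm, voxel_mm)
  s / smoothed_noise_sd_map(dim, fwhm, voxel_mm)
}

smallest_calibrated_extent <- function(samples, alpha) {
  for (k in seq_len(max(samples) + 1)) {
    if (mean(samples >= k) <= alpha) return(as.integer(k))
  }
  abort_arg("alpha unattainable on this grid")  # unreachable: P(max >= max+1) = 0
}

#' Cluster table in mm coordinates
#'
#' Thresholds a signed Z map two-sided at `voxel_p`, keeps clusters of at
#' least `extent_k` voxels, and reports one row per surviving cluster:
#' peak mm coordinates (via the grid affine), voxel count, and the signed
#' peak Z. Rows are sorted positive clusters first, then by peak
#' coordinates.
#'
#' @param zmap Numeric 3-D array of signed Z values (or a vector matching
#'   the grid).
#' @param grid An [fc_grid()].
#' @param voxel_p Two-sided voxelwise probability threshold.
#' @param extent_k Minimum cluster extent (voxels), `>= 1`.
#' @param connectivity See [neighbor_offsets()].
#' @return data.frame with `x`, `y`, `z` (mm), `voxels`, `peak_z`, `sign`.
#' @export
cluster_table <- function(zmap, grid, voxel_p = 0.001, extent_k = 1,
                          connectivity = "faces") {
  if (extent_k < 1) abort_arg("extent_k must be >= 1")
  if (!is.array(zmap)) zmap <- array(zmap, grid$dim)
  zc <- stats::qnorm(1 - voxel_p / 2)
  lab <- label_clusters(zmap, threshold = zc, connectivity = connectivity)
  cl <- lab$clusters[lab$clusters$size >= extent_k, , drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      voxels = integer(0), peak_z = numeric(0),
                      sign = integer(0)))
  mm <- voxel_to_mm(grid, as.matrix(cl[, c("peak_i", "peak_j", "peak_k")]))
  out <- data.frame(x = mm[, 1], y = mm[, 2], z = mm[, 3],
                    voxels = cl$size, peak_z = cl$peak_value, sign = cl$sign)
  out[order(-out$sign, out$x, out$y, out$z), , drop = FALSE]
}
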