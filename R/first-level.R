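#' Double-gamma hemodynamic response parameters
#'
#' Canonical double-gamma: a positive gamma density peaking near
#' `peak_delay` seconds minus an undershoot gamma scaled by `ratio`.
#' Both dispersions are in seconds; `dt` is the oversampling interval used
#' when convolving trial boxcars.
#'
#' @param peak_delay,peak_disp Delay (s) and dispersion of the response peak.
#' @param undershoot_delay,undershoot_disp Delay and dispersion of the
#'   undershoot.
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param amplitude Overall scaling.
#' @param dt Oversampling interval (s).
#' @param length_s Kernel support (s).
#' @export
hrf_spec <- function(peak_delay = 6, peak_disp = 1, undershoot_delay = 16,
                     undershoot_disp = 1, ratio = 1/6, amplitude = 1,
                     dt = 0.1, length_s = 32) {
  list(peak_delay = peak_delay, peak_disp = peak_disp,
       undershoot_delay = undershoot_delay, undershoot_disp = undershoot_disp,
       ratio = ratio, amplitude = amplitude, dt = dt, length_s = length_s)
}

#' Evaluate the canonical double-gamma HRF
#'
#' @param t Time(s) in seconds, all `>= 0`.
#' @param spec See [hrf_spec()].
#' @return Response values, 0 at `t = 0`.
#' @export
canonical_hrf <- function(t, spec = hrf_spec()) {
  if (any(t < 0)) abort_arg("t must be non-negative")
  spec$amplitude *
    (stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                   scale = spec$peak_disp) -
       spec$ratio * stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                                  scale = spec$undershoot_disp))
}

#' Unit-amplitude task regressor for one run
#'
#' Every trial enters as a unit-height boxcar of its stimulus duration
#' (targets and non-targets identically), convolved with the HRF on an
#' oversampled grid and sampled at volume acquisition times.
#'
#' @param schedule An `fc_schedule`.
#' @param n_vols Volumes in the run.
#' @param tr Repetition time (s).
#' @param hrf See [hrf_spec()].
#' @return Numeric vector of length `n_vols`.
#' @export
task_regressor <- function(schedule, n_vols = 140, tr = 2, hrf = hrf_spec()) {
  dt <- hrf$dt
  n_fine <- ceiling((schedule$run_length + hrf$length_s) / dt)
  u <- numeric(n_fine)
  for (i in seq_along(schedule$onsets)) {
    a <- floor(schedule$onsets[i] / dt) + 1L
    b <- min(n_fine, ceiling((schedule$onsets[i] + schedule$durations[i]) / dt))
    u[a:b] <- 1
  }
  h <- canonical_hrf(seq(0, hrf$length_s, by = dt), hrf)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- floor(((seq_len(n_vols) - 1L) * tr) / dt) + 1L
  conv[vol_idx]
}

# Legendre polynomial basis (orders 0..order) on n equally spaced points
# spanning [-1, 1]; order 0 is the intercept.
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) for (k in 2:order)
    P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  P
}

# Discrete cosine basis including the constant term.
dct_basis <- function(n, order) {
  t <- seq_len(n) - 0.5
  sapply(0:order, function(k) cos(pi * k * t / n))
}

# Nuisance columns taken from an expanded confounds table for the
# deconvolution model: motion + derivatives, FD, tissue signals +
# derivatives. (Quadratic terms stay in the table but are not regressors.)
glm_nuisance_columns <- function() {
  mot <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  c(mot, paste0(mot, "_derivative1"), "framewise_displacement",
    "csf", "white_matter", "global_signal",
    "csf_derivative1", "white_matter_derivative1", "global_signal_derivative1")
}

#' Build the concatenated four-run deconvolution design
#'
#' One unit-amplitude task regressor spans all runs of a condition; signal
#' drift (per-run polynomial basis, order 0 = run intercept) and the
#' nuisance regressors are run-blocked: zero outside their run.
#'
#' @param schedules List of `fc_schedule`, all the same condition.
#' @param confounds_list List of expanded confound tables, one per run.
#' @param n_vols Volumes per run.
#' @param tr Repetition time (s).
#' @param drift_order Polynomial drift order per run (0 = intercept only).
#' @param drift_basis `"legendre"` (default) or `"dct"`.
#' @param hrf See [hrf_spec()].
#' @param nuisance Include the confound regressors?
#' @return An object of class `fc_design`: the matrix (`X`), run index per
#'   row, and the condition label.
#' @export
build_design <- function(schedules, confounds_list, n_vols = 140, tr = 2,
                         drift_order = 3, drift_basis = c("legendre", "dct"),
                         hrf = hrf_spec(), nuisance = TRUE) {
  drift_basis <- match.arg(drift_basis)
  conds <- vapply(schedules, function(s) s$condition, character(1))
  if (length(unique(conds)) != 1L)
    abort_arg("all schedules must share one condition; got: ",
              paste(unique(conds), collapse = ", "))
  n_runs <- length(schedules)
  if (nuisance && length(confounds_list) != n_runs)
    abort_arg("need one confounds table per run")

  task <- unlist(lapply(schedules, task_regressor, n_vols = n_vols, tr = tr,
                        hrf = hrf))
  drift1 <- if (drift_basis == "legendre") legendre_basis(n_vols, drift_order)
            else dct_basis(n_vols, drift_order)
  blocks <- list(matrix(task, ncol = 1,
                        dimnames = list(NULL, "task")))
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_vols + seq_len(n_vols)
    drift <- matrix(0, n_runs * n_vols, ncol(drift1))
    drift[rows, ] <- drift1
    colnames(drift) <- sprintf("run%d_drift%d", r, 0:drift_order)
    blocks[[length(blocks) + 1L]] <- drift
    if (nuisance) {
      cn <- glm_nuisance_columns()
      cf <- confounds_list[[r]]
      missing_cols <- setdiff(cn, names(cf))
      if (length(missing_cols))
        abort_arg("confounds table for run ", r, " lacks: ",
                  paste(missing_cols, collapse = ", "))
      nm <- matrix(0, n_runs * n_vols, length(cn))
      nm[rows, ] <- as.matrix(cf[, cn])
      colnames(nm) <- sprintf("run%d_%s", r, cn)
      blocks[[length(blocks) + 1L]] <- nm
    }
  }
  X <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(X))) abort_arg("duplicate design column labels")
  zero_cols <- colnames(X)[colSums(abs(X)) == 0]
  if (length(zero_cols))
    abort_arg("all-zero design columns: ", paste(zero_cols, collapse = ", "))
  structure(list(X = X,
                 run_index = rep(seq_len(n_runs), each = n_vols),
                 condition = conds[1], n_vols = n_vols, tr = tr),
            class = "fc_design")
}

#' @export
print.fc_design <- function(x, ...) {
  cat(sprintf("<fc_design> %s: %d rows x %d columns (%d runs)\n",
              x$condition, nrow(x$X), ncol(x$X), max(x$run_index)))
  invisible(x)
}

#' Fit the voxelwise deconvolution GLM and save its residuals
#'
#' Ordinary least squares per voxel on the concatenated design. The design
#' is checked for collinearity first (singular values below
#' `rank_tol` x largest); an informative error names the dependent columns.
#'
#' @param Y Numeric matrix, volumes x voxels (concatenated runs).
#' @param design An `fc_design` or plain design matrix with column names.
#' @param rank_tol Relative singular-value tolerance for rank checks.
#' @return List with `beta` (coefficients x voxels), `residuals`
#'   (volumes x voxels), and `design`.
#' @export
fit_glm <- function(Y, design, rank_tol = 1e-10) {
  X <- if (inherits(design, "fc_design")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    abort_arg("rows of Y (", nrow(Y), ") != rows of design (", nrow(X), ")")
  sv <- svd(X, nu = 0, nv = ncol(X))
  bad <- sv$d < rank_tol * sv$d[1]
  if (any(bad)) {
    # columns loading on the null space identify the collinear set
    load <- rowSums(abs(sv$v[, bad, drop = FALSE]))
    culprits <- colnames(X)[load > 1e-6 * max(load)]
    stop("rank-deficient design; collinear columns: ",
         paste(culprits, collapse = ", "), call. = FALSE)
  }
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  rownames(beta) <- colnames(X)
  list(beta = beta, residuals = resid, design = design)
}

#' Percent signal change relative to a reference mean
#'
#' `100 * (x - ref) / ref`. For raw series the reference is the series mean;
#' for residual series the convention is the mean of the corresponding raw
#' (pre-residualization) voxel time course over the run.
#'
#' @param x Numeric vector/matrix.
#' @param reference Reference mean(s); must be positive. Default: `mean(x)`.
#' @return Same shape as `x`, in percent units.
#' @export
percent_signal_change <- function(x, reference = NULL) {
  if (is.null(reference)) reference <- mean(x)
  if (any(reference <= 0)) abort_arg("reference mean must be positive")
  if (is.matrix(x) && length(reference) == ncol(x))
    return(sweep(sweep(x, 2, reference, "-"), 2, reference, "/") * 100)
  100 * (x - reference) / reference
}
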