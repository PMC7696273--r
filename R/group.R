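#' Mean-center a covariate within group
#'
#' Subtracts the within-group mean (computed over the supplied, i.e.
#' retained, values). Idempotent; each group's centered values sum to ~0.
#'
#' @param values Numeric covariate (e.g. transformed run fatigue).
#' @param group Factor/character of the same length.
#' @return Numeric vector of centered values.
#' @export
mean_center_by_group <- function(values, group) {
  group <- as.factor(group)
  if (length(values) != length(group)) abort_arg("length mismatch")
  if (any(table(group) == 0) || length(values) == 0)
    abort_arg("empty group")
  values - stats::ave(values, group)
}

#' Voxelwise fatigue mixed-effects map for one seed and one group
#'
#' Per voxel: `z ~ condition + fatigue_c + condition:fatigue_c + run`
#' with a random subject intercept, fitted by REML
#' (see [lmm_mass_ranint()]). The reported map is the
#' `condition:fatigue_c` interaction — the 2-back minus 0-back fatigue
#' slope in Fisher-z units per covariate unit, positive when the 2-back
#' slope exceeds the 0-back slope. Rows excluded upstream (zero-fatigue
#' runs) are simply absent from `data`.
#'
#' @param zdata Observations x voxels matrix of Fisher-z values; one row
#'   per retained subject x condition x run map.
#' @param meta data.frame with one row per row of `zdata`: `subject_id`,
#'   `condition` (factor with levels `0-back`, `2-back`), `run_index`,
#'   `fatigue_c` (group-mean-centered covariate).
#' @param run_as Treat run as `"factor"` (default, 4 levels) or `"numeric"`.
#' @param stratified If `TRUE`, fit condition-stratified fatigue slopes
#'   (`condition + condition:fatigue_c + run`) instead of the common-slope
#'   parameterization; the reported contrast (slope difference) is the same.
#' @return Object of class `fc_statmap`: per-voxel `est`, `se`, `tstat`,
#'   `df`, `p`, the singular-fit count, and the model descriptor.
#' @export
voxelwise_fatigue_lme <- function(zdata, meta, run_as = c("factor", "numeric"),
                                  stratified = FALSE) {
  run_as <- match.arg(run_as)
  zdata <- as.matrix(zdata)
  need <- c("subject_id", "condition", "run_index", "fatigue_c")
  if (!all(need %in% names(meta)))
    abort_arg("meta must contain: ", paste(need, collapse = ", "))
  if (nrow(meta) != nrow(zdata)) abort_arg("meta rows != zdata rows")
  if (length(unique(meta$subject_id)) < 2L)
    abort_arg("need at least 2 subjects")
  meta$condition <- factor(meta$condition, levels = c("0-back", "2-back"))
  run <- if (run_as == "factor") factor(meta$run_index) else meta$run_index
  if (stratified) {
    X <- stats::model.matrix(~ condition + condition:fatigue_c + run,
                             data = cbind(meta, run = run))
    cvec <- numeric(ncol(X))
    cvec[match("condition2-back:fatigue_c", colnames(X))] <- 1
    cvec[match("condition0-back:fatigue_c", colnames(X))] <- -1
  } else {
    X <- stats::model.matrix(~ condition * fatigue_c + run,
                             data = cbind(meta, run = run))
    cvec <- "condition2-back:fatigue_c"
  }
  fit <- lmm_mass_ranint(zdata, X, meta$subject_id, contrast = cvec)
  structure(c(fit, list(model = if (stratified) "stratified-slopes"
                                else "condition-by-fatigue interaction",
                        run_as = run_as, n_obs = nrow(zdata),
                        n_subjects = length(unique(meta$subject_id)))),
            class = "fc_statmap")
}

#' @export
print.fc_statmap <- function(x, ...) {
  cat(sprintf(
    "<fc_statmap> %d voxels, %d obs / %d subjects; %s; %d singular fit(s)\n",
    length(x$est), x$n_obs, x$n_subjects, x$model, x$n_singular))
  invisible(x)
}

#' Signed Z equivalent of a stat map
#'
#' Converts each voxel's t statistic to the standard-normal deviate with
#' the same two-sided tail probability, keeping the sign: positive where
#' the 2-back fatigue slope exceeds the 0-back slope.
#'
#' @param statmap An `fc_statmap`.
#' @return Numeric vector of signed Z values.
#' @export
contrast_sign_convention <- function(statmap) {
  z <- sign(statmap$tstat) * stats::qnorm(statmap$p / 2, lower.tail = FALSE)
  z[statmap$tstat == 0] <- 0
  z
}
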