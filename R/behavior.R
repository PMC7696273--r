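#' Run-level fatigue scores from VAS-F ratings
#'
#' Run k's fatigue is the mean of the rating before it (index k-1) and the
#' rating after it (index k). Runs in which the participant reported no
#' fatigue both before and after (both ratings exactly 0) are flagged
#' `excluded`, since their signal cannot reflect fatigue.
#'
#' @param vasf data.frame from [generate_vasf()] (or equivalent) with
#'   `subject_id`, `condition`, `rating_index` 0..4, `score`.
#' @return data.frame with one row per subject x condition x run (1..4):
#'   `pre_score`, `post_score`, `run_mean`, `excluded`.
#' @export
compute_run_fatigue <- function(vasf) {
  need <- c("subject_id", "condition", "rating_index", "score")
  if (!all(need %in% names(vasf)))
    abort_arg("vasf must contain: ", paste(need, collapse = ", "))
  key <- interaction(vasf$subject_id, vasf$condition, drop = TRUE)
  counts <- table(key)
  full <- tapply(vasf$rating_index, key,
                 function(ix) length(ix) == 5L && setequal(ix, 0:4))
  if (!all(unlist(full))) {
    bad <- names(full)[!unlist(full)]
    abort_arg("incomplete rating sets (need indices 0..4) for: ",
              paste(bad, collapse = ", "))
  }
  ord <- order(vasf$subject_id, vasf$condition, vasf$rating_index)
  v <- vasf[ord, ]
  out <- do.call(rbind, lapply(split(v, interaction(v$subject_id, v$condition,
                                                    drop = TRUE)),
    function(d) {
      s <- d$score[match(0:4, d$rating_index)]
      data.frame(subject_id = d$subject_id[1], condition = d$condition[1],
                 run_index = 1:4,
                 pre_score = s[1:4], post_score = s[2:5],
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out$run_mean <- (out$pre_score + out$post_score) / 2
  out$excluded <- out$pre_score == 0 & out$post_score == 0
  out
}

# Box-Cox profile log-likelihood for a positive sample at a given lambda.
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- boxcox_transform(x, lambda)
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(log(x))
}

#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda`, or `log(x)` at `lambda = 0`. Monotone
#' increasing in `x` for any `lambda`.
#'
#' @param x Positive values.
#' @param lambda Exponent.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) abort_arg("Box-Cox requires strictly positive values")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Maximum-likelihood Box-Cox transformation
#'
#' Estimates the exponent by maximizing the profile log-likelihood over
#' `interval` and returns the transformed values.
#'
#' @param x Positive values.
#' @param interval Search interval for lambda.
#' @return List of class `fc_boxcox`: `lambda`, `transformed`, `loglik`.
#' @export
boxcox_mle <- function(x, interval = c(-2, 2)) {
  if (any(x <= 0)) abort_arg("Box-Cox requires strictly positive values")
  opt <- stats::optimize(function(l) boxcox_loglik(x, l), interval,
                         maximum = TRUE, tol = 1e-6)
  structure(list(lambda = opt$maximum,
                 transformed = boxcox_transform(x, opt$maximum),
                 loglik = opt$objective),
            class = "fc_boxcox")
}

#' Add Box-Cox-transformed fatigue to a run-fatigue table
#'
#' The exponent is estimated once on the pooled retained (non-excluded)
#' run means; excluded runs get `NA`.
#'
#' @param run_fatigue Output of [compute_run_fatigue()].
#' @return The table with columns `transformed` and attribute `"lambda"`.
#' @export
add_transformed_fatigue <- function(run_fatigue) {
  keep <- !run_fatigue$excluded
  if (!any(keep)) abort_arg("all runs excluded; nothing to transform")
  bc <- boxcox_mle(run_fatigue$run_mean[keep])
  run_fatigue$transformed <- NA_real_
  run_fatigue$transformed[keep] <- bc$transformed
  attr(run_fatigue, "lambda") <- bc$lambda
  run_fatigue
}

#' Fit the behavioral linear mixed model
#'
#' REML fit of `response ~ group * condition * covariate` with a random
#' subject intercept, Satterthwaite degrees of freedom throughout
#' (including the post hoc contrasts via [pairwise_contrasts()]).
#'
#' @param data data.frame with columns `subject_id`, `group`, `condition`,
#'   the response, and the covariate (`run_index` or transformed fatigue
#'   `fatigue_t`).
#' @param response One of `"vasf"`, `"accuracy"`, `"rt"`; resolved to
#'   columns `transformed`/`vasf`, `accuracy`, `mean_rt`.
#' @param covariate `"run"` (4-level factor) or `"fatigue"` (continuous
#'   `fatigue_t`).
#' @return Object of class `fc_lme`: the `lmerTest` fit, its fixed-effect
#'   table, and a singular-fit flag.
#' @export
fit_behavior_lme <- function(data, response = c("vasf", "accuracy", "rt"),
                             covariate = c("run", "fatigue")) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  ycol <- switch(response,
                 vasf = if ("transformed" %in% names(data)) "transformed" else "vasf",
                 accuracy = "accuracy", rt = "mean_rt")
  xcol <- if (covariate == "run") "run_index" else "fatigue_t"
  need <- c("subject_id", "group", "condition", ycol, xcol)
  if (!all(need %in% names(data)))
    abort_arg("data must contain: ", paste(need, collapse = ", "))
  d <- data
  d$.y <- d[[ycol]]
  d$.x <- if (covariate == "run") factor(d$run_index) else d[[xcol]]
  d$group <- factor(d$group)
  d$condition <- factor(d$condition)
  d <- d[stats::complete.cases(d[, c(".y", ".x", "subject_id")]), ]
  if (length(unique(d$subject_id[d$group == levels(d$group)[1]])) < 2 ||
      length(unique(d$subject_id[d$group == levels(d$group)[2]])) < 2)
    abort_arg("need at least 2 subjects per group")
  fit <- tryCatch(
    lmerTest::lmer(.y ~ group * condition * .x + (1 | subject_id),
                   data = d, REML = TRUE),
    error = function(e)
      # degenerate responses (e.g. zero variance) can defeat the Satterthwaite
      # machinery; keep the plain REML fit and report df as NA
      lme4::lmer(.y ~ group * condition * .x + (1 | subject_id),
                 data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular mixed-model fit (random-intercept variance ~0)")
  ctab <- tryCatch(as.data.frame(stats::coef(summary(fit))),
                   error = function(e) NULL)
  if (is.null(ctab)) {
    est <- lme4::fixef(fit)
    se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit, use.hessian = FALSE)))),
                   error = function(e) rep(NA_real_, length(est)))
    ctab <- data.frame(Estimate = est, `Std. Error` = se, row.names = names(est),
                       check.names = FALSE)
  }
  if (!"df" %in% names(ctab)) {
    ctab$df <- NA_real_
    ctab[["Pr(>|t|)"]] <- NA_real_
  }
  structure(list(fit = fit,
                 coefficients = ctab,
                 response = response, covariate = covariate,
                 singular = singular),
            class = "fc_lme")
}

#' @export
print.fc_lme <- function(x, ...) {
  cat(sprintf("<fc_lme> %s ~ group * condition * %s + (1|subject)%s\n",
              x$response, x$covariate,
              if (x$singular) "  [singular]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tukey-adjusted post hoc contrasts
#'
#' Pairwise comparisons of estimated marginal means (or of fatigue slopes,
#' for the interaction follow-up) with Tukey multiplicity adjustment and
#' Satterthwaite degrees of freedom.
#'
#' @param fit An `fc_lme`.
#' @param by One-sided formula naming the factor(s) to compare, e.g.
#'   `~ condition | group`.
#' @param slopes If `TRUE`, compare the slopes of the continuous covariate
#'   (`emtrends`) instead of marginal means.
#' @return data.frame of contrasts with adjusted p-values; for
#'   `slopes = TRUE` the per-level slope estimates are attached as
#'   attribute `"trends"`.
#' @export
pairwise_contrasts <- function(fit, by, slopes = FALSE) {
  stopifnot(inherits(fit, "fc_lme"))
  vars <- all.vars(by)
  have <- c("group", "condition", ".x")
  if (!all(vars %in% have))
    abort_arg("factor(s) not in fit: ",
              paste(setdiff(vars, have), collapse = ", "))
  emmeans::emm_options(lmer.df = "satterthwaite", lmerTest.limit = 1e5)
  if (slopes) {
    if (fit$covariate != "fatigue")
      abort_arg("slope contrasts need the continuous fatigue covariate")
    tr <- emmeans::emtrends(fit$fit, specs = by, var = ".x")
    out <- as.data.frame(summary(emmeans::contrast(tr, method = "pairwise",
                                                   adjust = "tukey")))
    attr(out, "trends") <- as.data.frame(summary(tr))
    out
  } else {
    em <- emmeans::emmeans(fit$fit, specs = by)
    as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                            adjust = "tukey")))
  }
}
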