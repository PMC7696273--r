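#' Generate a two-group study cohort
#'
#' Draws per-subject random intercepts (latent units) used throughout the
#' generators. Group sizes default to the study design: 26 people with
#' multiple sclerosis (MS) and 14 healthy controls (HC).
#'
#' @param n_ms,n_hc Number of subjects per group (non-negative).
#' @param between_subject_sd SD of the latent subject intercepts.
#' @param rng_seed Integer seed; the cohort is a pure function of it.
#' @return A data.frame with columns `subject_id`, `group` (factor MS/HC)
#'   and `subject_intercept`.
#' @export
generate_cohort <- function(n_ms = 26, n_hc = 14, between_subject_sd = 0.5,
                            rng_seed = NULL) {
  if (length(n_ms) != 1 || length(n_hc) != 1 || n_ms < 0 || n_hc < 0)
    abort_arg("n_ms and n_hc must be scalar counts >= 0")
  n_ms <- as.integer(n_ms); n_hc <- as.integer(n_hc)
  n <- n_ms + n_hc
  with_rng_seed(rng_seed, {
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n) + 0L)[seq_len(n)],
      group = factor(rep(c("MS", "HC"), c(n_ms, n_hc)), levels = c("MS", "HC")),
      subject_intercept = stats::rnorm(n, 0, between_subject_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate one jittered n-back run schedule
#'
#' 65 letter trials per run, each 1.5 s of stimulus followed by a 0.5 s base
#' inter-trial interval (a 2 s trial slot). Six null events, each a positive
#' multiple of the 2 s trial length, are inserted between successive trials
#' at random gap positions; their total duration closes the run to exactly
#' `run_length` seconds. A letter stream (17 high-discriminability letters)
#' is drawn so that target trials are defined as in the task: the letter "K"
#' for 0-back, a letter matching the one two trials earlier for 2-back.
#'
#' @param condition `"0-back"` or `"2-back"`.
#' @param run_index Run number 1..4.
#' @param rng_seed Integer seed; the schedule is a pure function of it.
#' @param n_trials,stim_dur,iti,n_null,run_length Timing protocol; defaults
#'   are the study protocol. With `n_null = 0` the budget must close exactly
#'   (`run_length == n_trials * (stim_dur + iti)`), giving a strictly
#'   periodic schedule.
#' @return An object of class `fc_schedule`.
#' @export
generate_task_schedule <- function(condition = c("0-back", "2-back"),
                                   run_index = 1L, rng_seed = NULL,
                                   n_trials = 65L, stim_dur = 1.5, iti = 0.5,
                                   n_null = 6L, run_length = 260) {
  condition <- match.arg(condition)
  trial_len <- stim_dur + iti
  null_total <- run_length - n_trials * trial_len
  if (null_total < 0)
    abort_arg("impossible timing budget: trials alone exceed run_length")
  null_units <- null_total / trial_len
  if (abs(null_units - round(null_units)) > 1e-9)
    abort_arg("impossible timing budget: null time is not a multiple of the trial length")
  null_units <- as.integer(round(null_units))
  if (n_null == 0 && null_units != 0)
    abort_arg("impossible timing budget: zero null events cannot fill ",
              null_total, " s")
  if (n_null > 0 && null_units < n_null)
    abort_arg("impossible timing budget: need at least one trial-length unit per null event")

  with_rng_seed(rng_seed, {
    if (n_null > 0) {
      # uniform composition of null_units into n_null positive parts
      cuts <- sort(sample.int(null_units - 1L, n_null - 1L))
      parts <- diff(c(0L, cuts, null_units))
      null_durs <- parts * trial_len
      gap_pos <- sort(sample.int(n_trials - 1L, n_null))  # after trial gap_pos
    } else {
      null_durs <- numeric(0)
      gap_pos <- integer(0)
    }
    letters17 <- c("A", "B", "C", "D", "F", "H", "J", "K", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "Z")
    stim <- sample(letters17, n_trials, replace = TRUE)

    onsets <- numeric(n_trials)
    t <- 0
    for (i in seq_len(n_trials)) {
      onsets[i] <- t
      t <- t + trial_len
      hit <- match(i, gap_pos)
      if (!is.na(hit)) t <- t + null_durs[hit]
    }
    target_flags <- if (condition == "0-back") {
      stim == "K"
    } else {
      c(FALSE, FALSE, stim[-c(1, 2)][seq_len(n_trials - 2)] ==
          stim[seq_len(n_trials - 2)])
    }
    structure(list(condition = condition, run_index = as.integer(run_index),
                   onsets = onsets, durations = rep(stim_dur, n_trials),
                   iti = iti, letters = stim, target_flags = target_flags,
                   null_durations = null_durs, null_after_trial = gap_pos,
                   run_length = run_length),
              class = "fc_schedule")
  })
}

#' @export
print.fc_schedule <- function(x, ...) {
  cat(sprintf("<fc_schedule> %s run %d: %d trials, %d null events, %g s\n",
              x$condition, x$run_index, length(x$onsets),
              length(x$null_durations), x$run_length))
  invisible(x)
}

#' Events table (BIDS-style) for a schedule
#' @param schedule An `fc_schedule`.
#' @return data.frame with `onset`, `duration`, `trial_type`.
#' @export
events_table <- function(schedule) {
  data.frame(onset = schedule$onsets,
             duration = schedule$durations,
             trial_type = ifelse(schedule$target_flags, "target", "nontarget"),
             stringsAsFactors = FALSE)
}

#' Default effect parameters for the fatigue-rating generator
#'
#' Units are VAS-F points (0-100 scale) on the latent (pre-clipping) scale.
#' Defaults are chosen to echo the study's descriptives: a large MS-vs-HC
#' shift, a slight excess of fatigue in the 0-back condition for MS, and
#' fatigue accumulating over successive ratings within a condition block.
#'
#' @param baseline Latent score at the first rating for an average HC subject.
#' @param ms_offset Added for the MS group.
#' @param cond_offset_2back Added in the 2-back condition.
#' @param rating_trend Added per rating index (0..4) as fatigue accrues.
#' @param subject_scale Multiplier mapping cohort `subject_intercept` (latent
#'   units) onto VAS-F points.
#' @param noise_sd Rating noise SD.
#' @export
vasf_params <- function(baseline = 18, ms_offset = 22, cond_offset_2back = -2,
                        rating_trend = 3.5, subject_scale = 16, noise_sd = 7) {
  list(baseline = baseline, ms_offset = ms_offset,
       cond_offset_2back = cond_offset_2back, rating_trend = rating_trend,
       subject_scale = subject_scale, noise_sd = noise_sd)
}

#' Generate VAS-F fatigue ratings
#'
#' Five ratings per subject and condition (index 0 before the first run,
#' 1..4 after each run), built additively on the latent scale and clipped to
#' the 0-100 response scale.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params See [vasf_params()].
#' @param rng_seed Integer seed.
#' @return data.frame with `subject_id`, `group`, `condition`,
#'   `rating_index`, `score`.
#' @export
generate_vasf <- function(cohort, params = vasf_params(), rng_seed = NULL) {
  grid <- expand.grid(rating_index = 0:4,
                      condition = c("0-back", "2-back"),
                      subject_id = cohort$subject_id,
                      stringsAsFactors = FALSE)
  grid$group <- cohort$group[match(grid$subject_id, cohort$subject_id)]
  subj_int <- cohort$subject_intercept[match(grid$subject_id, cohort$subject_id)]
  with_rng_seed(rng_seed, {
    latent <- params$baseline +
      params$ms_offset * (grid$group == "MS") +
      params$cond_offset_2back * (grid$condition == "2-back") +
      params$rating_trend * grid$rating_index +
      params$subject_scale * subj_int +
      stats::rnorm(nrow(grid), 0, params$noise_sd)
    grid$score <- pmin(100, pmax(0, latent))
    grid[, c("subject_id", "group", "condition", "rating_index", "score")]
  })
}

#' Default parameters for the behavioral generator
#'
#' Accuracy slopes are per standardized run-fatigue unit and mirror the
#' pattern the design is built to detect: no fatigue-accuracy relation in
#' 0-back, opposite-signed 2-back slopes in the two groups. Response times
#' are in milliseconds with a large 2-back cost.
#' @param acc_base_0back,acc_base_2back Baseline accuracy by condition.
#' @param acc_slopes Named list `group.condition` -> slope per standardized
#'   fatigue unit.
#' @param acc_noise_sd Accuracy noise SD.
#' @param rt_base,rt_2back_cost,rt_noise_sd Response-time parameters (ms).
#' @export
behavior_params <- function(acc_base_0back = 0.97, acc_base_2back = 0.90,
                            acc_slopes = list("HC.0-back" = 0,
                                              "HC.2-back" = 0.021,
                                              "MS.0-back" = 0,
                                              "MS.2-back" = -0.016),
                            acc_noise_sd = 0.03,
                            rt_base = 480, rt_2back_cost = 148,
                            rt_noise_sd = 60) {
  list(acc_base_0back = acc_base_0back, acc_base_2back = acc_base_2back,
       acc_slopes = acc_slopes, acc_noise_sd = acc_noise_sd,
       rt_base = rt_base, rt_2back_cost = rt_2back_cost,
       rt_noise_sd = rt_noise_sd)
}

#' Generate per-run task performance tied to run-level fatigue
#'
#' @param cohort Output of [generate_cohort()].
#' @param run_fatigue Output of [compute_run_fatigue()] on the cohort's
#'   ratings (all runs; the standardized `run_mean` drives the slopes).
#' @param params See [behavior_params()].
#' @param rng_seed Integer seed.
#' @return data.frame with `subject_id`, `group`, `condition`, `run_index`,
#'   `accuracy`, `mean_rt`.
#' @export
generate_behavior <- function(cohort, run_fatigue, params = behavior_params(),
                              rng_seed = NULL) {
  rf <- run_fatigue
  rf$group <- cohort$group[match(rf$subject_id, cohort$subject_id)]
  fat_std <- as.numeric(scale(rf$run_mean))
  if (anyNA(fat_std)) fat_std[] <- 0  # constant fatigue: no slope axis
  key <- paste(rf$group, rf$condition, sep = ".")
  slope <- vapply(key, function(k) {
    s <- params$acc_slopes[[k]]
    if (is.null(s)) 0 else s
  }, numeric(1))
  with_rng_seed(rng_seed, {
    acc <- ifelse(rf$condition == "2-back",
                  params$acc_base_2back, params$acc_base_0back) +
      slope * fat_std + stats::rnorm(nrow(rf), 0, params$acc_noise_sd)
    rt <- params$rt_base +
      params$rt_2back_cost * (rf$condition == "2-back") +
      stats::rnorm(nrow(rf), 0, params$rt_noise_sd)
    data.frame(subject_id = rf$subject_id, group = rf$group,
               condition = rf$condition, run_index = rf$run_index,
               accuracy = pmin(1, pmax(0, acc)),
               mean_rt = pmax(50, rt),
               stringsAsFactors = FALSE)
  })
}
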