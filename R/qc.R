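#' Missing-sample mask for one eye
#'
#' A sample is missing when the tracker's validity code exceeds 1.
#'
#' @param trial One trial's gaze rows.
#' @param eye `"left"` or `"right"`.
#' @return Logical vector, `TRUE` where the sample is unusable.
#' @export
missing_mask <- function(trial, eye = c("left", "right")) {
  eye <- match.arg(eye)
  trial[[paste0("valid_", eye)]] > 1
}

longest_run <- function(mask) {
  if (length(mask) == 0 || !any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

qc_eye <- function(trial, eye, cfg) {
  m <- missing_mask(trial, eye)
  dt_ms <- 1000 / cfg$sampling_rate_hz
  first50 <- trial$t_ms < cfg$first50_ms
  list(
    missing_fraction = mean(m),
    longest_gap_ms = longest_run(m) * dt_ms,
    missing_first50_fraction = if (any(first50)) mean(m[first50]) else 0
  )
}

#' Trial exclusion decision
#'
#' Applies the three missing-data exclusion rules, each a strict inequality:
#' more than 10\% of samples missing; more than 100 ms missing contiguously
#' (run length times the nominal sample interval); more than 80\% missing in
#' the first 50 ms. Rules are evaluated per eye; by default a trial is
#' excluded if either eye trips any rule (`qc_eye_rule = "any"`).
#'
#' @param trial One trial's gaze rows.
#' @param cfg A [study_config()].
#' @param manual If `TRUE`, the trial is additionally excluded with reason
#'   `"manual"` (visual-inspection surrogate; see [qc_cohort()]).
#' @return A one-row data frame: trial key, per-eye missing statistics,
#'   `excluded` and a `;`-separated `reasons` string drawn from
#'   `frac_gt_10`, `gap_gt_100ms`, `first50_gt_80`, `manual`.
#' @export
exclusion_decision <- function(trial, cfg = study_config(), manual = FALSE) {
  ql <- qc_eye(trial, "left", cfg)
  qr <- qc_eye(trial, "right", cfg)
  rule <- function(f) {
    trips <- c(f(ql), f(qr))
    if (cfg$qc_eye_rule == "any") any(trips) else all(trips)
  }
  reasons <- character(0)
  if (rule(function(q) q$missing_fraction > cfg$max_missing_frac))
    reasons <- c(reasons, "frac_gt_10")
  if (rule(function(q) q$longest_gap_ms > cfg$max_gap_ms))
    reasons <- c(reasons, "gap_gt_100ms")
  if (rule(function(q) q$missing_first50_fraction > cfg$max_missing_first50_frac))
    reasons <- c(reasons, "first50_gt_80")
  if (isTRUE(manual)) reasons <- c(reasons, "manual")
  data.frame(
    subject_id = trial$subject_id[1], task = trial$task[1],
    direction = trial$direction[1], eccentricity = trial$eccentricity[1],
    trial_index = trial$trial_index[1],
    missing_fraction_left = ql$missing_fraction,
    missing_fraction_right = qr$missing_fraction,
    longest_gap_ms_left = ql$longest_gap_ms,
    longest_gap_ms_right = qr$longest_gap_ms,
    missing_first50_fraction_left = ql$missing_first50_fraction,
    missing_first50_fraction_right = qr$missing_first50_fraction,
    excluded = length(reasons) > 0,
    reasons = paste(reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Quality control over a whole gaze table
#'
#' Runs [exclusion_decision()] on every trial. The published procedure's
#' visual inspection of position-time diagrams is represented by an explicit
#' manual-exclusion list rather than an automatic surrogate.
#'
#' @param gaze A gaze sample table.
#' @param cfg A [study_config()].
#' @param manual_exclusions Optional data frame of trial keys
#'   (`subject_id, task, direction, eccentricity, trial_index`) to exclude
#'   with reason `"manual"`.
#' @return A QC report data frame, one row per trial.
#' @export
qc_cohort <- function(gaze, cfg = study_config(), manual_exclusions = NULL) {
  manual_keys <- character(0)
  if (!is.null(manual_exclusions))
    manual_keys <- as.character(trial_key(manual_exclusions))
  trials <- split_trials(gaze)
  rep <- do.call(rbind, lapply(names(trials), function(k)
    exclusion_decision(trials[[k]], cfg, manual = k %in% manual_keys)))
  rownames(rep) <- NULL
  rep
}

#' Interpolate missing samples within a trial
#'
#' Replaces each interior run of missing samples (validity code > 1) by
#' linear interpolation between the nearest valid neighbours, per eye and
#' per channel; leading and trailing missing runs are filled with the
#' nearest valid value. Valid samples are never altered. Filled samples are
#' flagged in new `interp_left` / `interp_right` columns so provenance is
#' auditable; validity codes themselves are left untouched.
#'
#' @param trial One trial's gaze rows (should have passed
#'   [exclusion_decision()]).
#' @return The trial with gap-free position channels and interpolation
#'   flags.
#' @export
interpolate_missing <- function(trial) {
  out <- trial
  for (eye in c("left", "right")) {
    m <- missing_mask(trial, eye)
    out[[paste0("interp_", eye)]] <- m
    if (!any(m)) next
    if (all(m))
      stop("trial has no valid samples on the ", eye, " eye", call. = FALSE)
    for (ch in paste0(c("x_", "y_"), eye)) {
      out[[ch]] <- if (sum(!m) == 1) rep(trial[[ch]][!m], nrow(trial))
                   else stats::approx(trial$t_ms[!m], trial[[ch]][!m],
                                      xout = trial$t_ms, rule = 2)$y
    }
  }
  out
}

#' @rdname interpolate_missing
#' @param gaze A gaze table; excluded trials (per `qc_report`) are dropped
#'   before interpolation.
#' @param qc_report Output of [qc_cohort()].
#' @return `interpolate_cohort()` returns the retained, interpolated gaze
#'   table.
#' @export
interpolate_cohort <- function(gaze, qc_report) {
  keep <- as.character(trial_key(qc_report[!qc_report$excluded, ]))
  trials <- split_trials(gaze)
  out <- do.call(rbind, lapply(trials[names(trials) %in% keep],
                               interpolate_missing))
  rownames(out) <- NULL
  out
}

#' Drop practice trials
#'
#' The first `practice_trials` trials of each condition (default 2) are
#' treated as practice and removed.
#'
#' @param gaze A gaze or metrics table carrying `trial_index`.
#' @param cfg A [study_config()].
#' @return The table without practice trials.
#' @export
drop_practice <- function(gaze, cfg = study_config()) {
  gaze[gaze$trial_index > cfg$practice_trials, , drop = FALSE]
}

#' Condition acceptance
#'
#' A condition is accepted when at least `min_trials_per_condition`
#' (default 9, half the 18 non-practice trials) adequate trials survive
#' practice removal, missing-data exclusion and detection gating.
#'
#' @param n_trials Number of surviving trials in the condition.
#' @param cfg A [study_config()].
#' @return Logical.
#' @export
accept_condition <- function(n_trials, cfg = study_config()) {
  n_trials >= cfg$min_trials_per_condition
}
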