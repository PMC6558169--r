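#' Saccade gain
#'
#' Ratio of the final eye position to the reference position: the target
#' itself for prosaccades, the mirror of the target for anti-saccades
#' (where the correct landing point is opposite the target). A signed
#' ratio; 1 = accurate, below 1 = hypometric.
#'
#' @param final_position_deg Eye position at saccade offset (deg, signed).
#' @param target_deg Signed target position (deg, non-zero).
#' @param task `"prosaccade"` or `"antisaccade"`.
#' @return Gain (dimensionless).
#' @export
compute_gain <- function(final_position_deg, target_deg, task) {
  if (any(target_deg == 0)) stop("target position must be non-zero",
                                 call. = FALSE)
  ref <- ifelse(task == "antisaccade", -target_deg, target_deg)
  final_position_deg / ref
}

#' Movement type of one eye for a saccade direction
#'
#' Adduction is rotation toward the nose: the left eye adducts on rightward
#' saccades and abducts on leftward ones; mirrored for the right eye.
#'
#' @param eye `"left"` or `"right"`.
#' @param saccade_direction `"left"` or `"right"` (movement, not target).
#' @return `"adduction"` or `"abduction"` (vectorised).
#' @export
movement_type <- function(eye, saccade_direction) {
  ifelse(eye == saccade_direction, "abduction", "adduction")
}

#' Anti-saccade correctness
#'
#' A correctly performed anti-saccade moves opposite the target side; a
#' primary saccade toward the target is a direction error.
#'
#' @param saccade_direction Direction of the primary saccade.
#' @param target_direction Target side.
#' @param task Task of the trial; must be `"antisaccade"`.
#' @return Logical (vectorised).
#' @export
antisaccade_correct <- function(saccade_direction, target_direction, task) {
  if (any(task != "antisaccade"))
    stop("correctness is defined for anti-saccade trials only", call. = FALSE)
  saccade_direction != target_direction
}

#' Per-trial, per-eye saccade metrics
#'
#' Reduces the detected events to the primary saccade of each eye and
#' derives the behavioural metrics: latency (ms), peak velocity (deg/s),
#' amplitude (deg), duration (ms), gain, movement type, and - for
#' anti-saccade trials - correctness of the trial's primary direction.
#' `adequate` marks trials with an accepted primary saccade on at least one
#' eye.
#'
#' @param events Output of [detect_cohort()].
#' @return A data frame, one row per (trial, eye) with a primary event.
#' @export
trial_metrics <- function(events) {
  prim <- events[events$primary, , drop = FALSE]
  if (nrow(prim) == 0)
    return(cbind(prim[0, c("subject_id", "group", "task", "target_direction",
                           "eccentricity", "trial_index", "eye")],
                 data.frame(latency_ms = numeric(0),
                            peak_velocity_deg_s = numeric(0),
                            amplitude_deg = numeric(0),
                            duration_ms = numeric(0), gain = numeric(0),
                            movement_type = character(0),
                            saccade_direction = character(0),
                            correct = logical(0), adequate = logical(0))))
  target_deg <- ifelse(prim$target_direction == "left", -1, 1) *
    prim$eccentricity
  # trial-level primary direction: the earlier of the two eyes' primaries
  key <- interaction(prim[c("subject_id", "task", "target_direction",
                            "eccentricity", "trial_index")], drop = TRUE)
  first_dir <- tapply(seq_len(nrow(prim)), key, function(i)
    prim$direction[i][which.min(prim$onset_ms[i])])
  trial_dir <- as.character(first_dir[as.character(key)])
  out <- data.frame(
    subject_id = prim$subject_id, group = prim$group, task = prim$task,
    target_direction = prim$target_direction,
    eccentricity = prim$eccentricity, trial_index = prim$trial_index,
    eye = prim$eye,
    latency_ms = prim$onset_ms,
    peak_velocity_deg_s = prim$peak_velocity_deg_s,
    amplitude_deg = prim$amplitude_deg,
    duration_ms = prim$duration_ms,
    gain = compute_gain(prim$final_position_deg, target_deg, prim$task),
    movement_type = movement_type(prim$eye, prim$direction),
    saccade_direction = prim$direction,
    correct = ifelse(prim$task == "antisaccade",
                     trial_dir != prim$target_direction, NA),
    adequate = TRUE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Anti-saccade performance of one subject
#'
#' Percentage of correctly performed anti-saccade trials among all adequate
#' anti-saccade trials (trials surviving QC with an accepted primary
#' saccade).
#'
#' @param metrics [trial_metrics()] rows of a single subject.
#' @return Performance in percent, or `NA` (flagged undefined) when the
#'   subject has no adequate anti-saccade trial.
#' @export
antisaccade_performance <- function(metrics) {
  anti <- metrics[metrics$task == "antisaccade" & metrics$adequate, ,
                  drop = FALSE]
  if (nrow(anti) == 0) return(NA_real_)
  # one row per trial (eyes agree on trial-level correctness by definition)
  trials <- anti[!duplicated(anti[c("target_direction", "eccentricity",
                                    "trial_index")]), , drop = FALSE]
  100 * mean(trials$correct)
}

#' Pro-/anti-saccade task differences of one subject
#'
#' Oculomotor-decision measures: `latency_difference_ms` = mean anti-saccade
#' latency minus mean prosaccade latency; `peak_velocity_difference_deg_s` =
#' mean prosaccade peak velocity minus mean anti-saccade peak velocity; the
#' scaled variant divides each trial's peak velocity by its amplitude
#' (main-sequence normalisation) before averaging. Trials with zero
#' amplitude are skipped from the scaled variant with a warning.
#'
#' @param metrics [trial_metrics()] rows of a single subject (accepted
#'   trials).
#' @return A one-row data frame; `NA` values when a task is missing.
#' @export
task_differences <- function(metrics) {
  pro <- metrics[metrics$task == "prosaccade", , drop = FALSE]
  anti <- metrics[metrics$task == "antisaccade", , drop = FALSE]
  if (nrow(pro) == 0 || nrow(anti) == 0)
    return(data.frame(latency_difference_ms = NA_real_,
                      peak_velocity_difference_deg_s = NA_real_,
                      scaled_peak_velocity_difference = NA_real_))
  scaled <- function(df) {
    zero <- df$amplitude_deg == 0
    if (any(zero))
      warning("skipping ", sum(zero),
              " zero-amplitude trial(s) from the scaled peak velocity",
              call. = FALSE)
    df <- df[!zero, , drop = FALSE]
    if (nrow(df) == 0) return(NA_real_)
    mean(df$peak_velocity_deg_s / df$amplitude_deg)
  }
  data.frame(
    latency_difference_ms = mean(anti$latency_ms) - mean(pro$latency_ms),
    peak_velocity_difference_deg_s =
      mean(pro$peak_velocity_deg_s) - mean(anti$peak_velocity_deg_s),
    scaled_peak_velocity_difference = scaled(pro) - scaled(anti)
  )
}

#' Per-subject condition summaries
#'
#' Mean latency, peak velocity and gain per subject x task x condition x
#' eye, with trial counts and the condition-acceptance decision (at least
#' `min_trials_per_condition` adequate trials).
#'
#' @param metrics Output of [trial_metrics()] (after [drop_practice()]).
#' @param cfg A [study_config()].
#' @return A data frame, one row per subject/task/condition/eye cell.
#' @export
subject_summary <- function(metrics, cfg = study_config()) {
  if (nrow(metrics) == 0) return(metrics)
  f <- interaction(metrics[c("subject_id", "task", "target_direction",
                             "eccentricity", "eye")], drop = TRUE)
  rows <- lapply(split(metrics, f), function(d) {
    n_trials <- length(unique(d$trial_index))
    data.frame(
      subject_id = d$subject_id[1], group = d$group[1], task = d$task[1],
      target_direction = d$target_direction[1],
      eccentricity = d$eccentricity[1], eye = d$eye[1],
      n_trials = n_trials,
      condition_accepted = accept_condition(n_trials, cfg),
      mean_latency_ms = mean(d$latency_ms),
      mean_peak_velocity_deg_s = mean(d$peak_velocity_deg_s),
      mean_gain = mean(d$gain),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$task, out$target_direction,
            out$eccentricity, out$eye), , drop = FALSE]
}

#' Long-format cohort summary table
#'
#' Melts the per-condition summaries into a tidy long table (one row per
#' subject, task, condition, eye and metric) ready for downstream group
#' statistics.
#'
#' @param summary Output of [subject_summary()].
#' @return A data frame with columns `subject_id, group, task,
#'   target_direction, eccentricity, eye, metric, value`, deterministically
#'   ordered.
#' @export
cohort_summary <- function(summary) {
  id_cols <- c("subject_id", "group", "task", "target_direction",
               "eccentricity", "eye")
  metrics <- c("mean_latency_ms", "mean_peak_velocity_deg_s", "mean_gain")
  if (nrow(summary) == 0) {
    out <- cbind(summary[0, id_cols, drop = FALSE],
                 data.frame(metric = character(0), value = numeric(0)))
    return(out)
  }
  long <- do.call(rbind, lapply(metrics, function(m)
    cbind(summary[id_cols], metric = m, value = summary[[m]],
          stringsAsFactors = FALSE)))
  long <- long[order(long$subject_id, long$task, long$target_direction,
                     long$eccentricity, long$eye, long$metric), ,
               drop = FALSE]
  rownames(long) <- NULL
  long
}
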