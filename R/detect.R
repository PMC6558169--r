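#' Saccade-like candidate events from a velocity trace
#'
#' A candidate is any maximal run of samples whose absolute velocity exceeds
#' the threshold (default 50 deg/s) for at least `consecutive_points`
#' samples (default 2). Each run yields one candidate, anchored at its
#' absolute-velocity maximum, so a single saccade is never double-counted.
#'
#' @param vel Velocity trace (deg/s; `NA` outside the valid filter region).
#' @param cfg A [study_config()].
#' @return A data frame with `peak_index`, `peak_velocity` (signed),
#'   `run_start`, `run_end`, ordered by time.
#' @export
candidate_events <- function(vel, cfg = study_config()) {
  over <- !is.na(vel) & abs(vel) > cfg$velocity_threshold_deg_s
  empty <- data.frame(peak_index = integer(0), peak_velocity = numeric(0),
                      run_start = integer(0), run_end = integer(0))
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= cfg$consecutive_points
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  peak <- mapply(function(s, e) s - 1 + which.max(abs(vel[s:e])), starts, ends)
  data.frame(peak_index = as.integer(peak),
             peak_velocity = vel[peak],
             run_start = as.integer(starts),
             run_end = as.integer(ends))
}

#' Locate the onset of a saccade-like event
#'
#' Searches backward from the velocity peak, within `onset_search_ms`
#' (default 50 ms), for the point where the acceleration in the movement
#' direction returns to zero: the onset is the sample following the nearest
#' sign change (acceleration "was 0" between the two). If the acceleration
#' never reaches zero in the window, the sample of minimum absolute
#' acceleration is used as a fallback. If the search window extends outside
#' the valid filter region the event is flagged `edge`.
#'
#' @param acc Acceleration trace (deg/s^2).
#' @param peak_index Velocity-peak sample index.
#' @param move_sign +1 for rightward, -1 for leftward movement.
#' @param cfg A [study_config()].
#' @param valid_start First index of the valid filter region.
#' @param zero_tol Acceleration level treated as zero (deg/s^2). On noisy
#'   recordings an exact sign change fires early inside the baseline noise;
#'   [detect_trial()] passes the pre-event noise floor (MAD of the baseline
#'   acceleration) scaled by `onset_accel_tol_mad`, which is exactly 0 for
#'   noise-free data.
#' @return A list with `index` (onset sample) and `edge` (logical).
#' @export
locate_onset <- function(acc, peak_index, move_sign, cfg = study_config(),
                         valid_start = 1L, zero_tol = 0) {
  n_back <- round(cfg$onset_search_ms * cfg$sampling_rate_hz / 1000)
  lo <- peak_index - n_back
  edge <- lo < valid_start
  lo <- max(lo, valid_start)
  if (peak_index - 2 < lo)
    return(list(index = max(lo, peak_index - 1), edge = TRUE))
  onset <- NA_integer_
  for (j in seq(peak_index - 2, lo)) {
    if (move_sign * acc[j] <= zero_tol) { onset <- j + 1L; break }
  }
  if (is.na(onset)) {
    win <- lo:(peak_index - 1)
    onset <- win[which.min(abs(acc[win]))]
  }
  list(index = onset, edge = edge)
}

#' Locate the offset of a saccade-like event
#'
#' The offset is the first sample after the velocity peak at which the
#' velocity in the movement direction has returned to (or below) zero
#' (`offset_velocity_threshold_deg_s`, default 0). An event whose velocity
#' never returns to zero inside the valid region is flagged `edge`.
#'
#' @param vel Velocity trace (deg/s).
#' @param peak_index Velocity-peak sample index.
#' @param move_sign Movement direction sign.
#' @param cfg A [study_config()].
#' @param valid_end Last index of the valid filter region.
#' @return A list with `index` (offset sample; last valid index when
#'   flagged) and `edge` (logical).
#' @export
locate_offset <- function(vel, peak_index, move_sign, cfg = study_config(),
                          valid_end = length(vel)) {
  thr <- cfg$offset_velocity_threshold_deg_s
  j <- peak_index + 1L
  while (j <= valid_end) {
    if (move_sign * vel[j] <= thr) return(list(index = j, edge = FALSE))
    j <- j + 1L
  }
  list(index = valid_end, edge = TRUE)
}

#' Pre-saccadic fixation check
#'
#' A saccade is only accepted when a fixation precedes it: every sample from
#' the start of the valid region up to the sample before onset must lie
#' within `fixation_radius_deg` (default 1.5 deg, strict) of the fixation
#' cross, and the position range over that window must stay below
#' `fixation_drift_deg` (default 0.6 deg, strict).
#'
#' @param pos Position trace (deg).
#' @param onset_index Saccade onset sample.
#' @param fixation_point Cross position (deg; 0 = screen centre).
#' @param cfg A [study_config()].
#' @param valid_start First index of the valid filter region.
#' @return Logical; `FALSE` for an empty pre-onset window.
#' @export
fixation_precedes <- function(pos, onset_index, fixation_point = 0,
                              cfg = study_config(), valid_start = 1L) {
  win <- pos[seq_len(onset_index - 1)]
  win <- win[seq_along(win) >= valid_start]
  win <- win[!is.na(win)]
  if (length(win) == 0) return(FALSE)
  all(abs(win - fixation_point) < cfg$fixation_radius_deg) &&
    (max(win) - min(win)) < cfg$fixation_drift_deg
}

#' Acceptance gates for a located saccade event
#'
#' Applies the acceptance rules: latency within `[100, 600]` ms after
#' stimulus onset (inclusive), duration at least 12 ms (inclusive), a
#' preceding fixation, and no edge truncation. All failed gates are listed
#' in `rejection_reasons` (`latency_low`, `latency_high`, `too_short`,
#' `no_fixation`, `edge`).
#'
#' @param event A one-row event data frame (see [detect_trial()]).
#' @param has_fixation Result of [fixation_precedes()].
#' @param cfg A [study_config()].
#' @return The event with `accepted` and `rejection_reasons` filled in.
#' @export
accept_saccade <- function(event, has_fixation, cfg = study_config()) {
  reasons <- character(0)
  if (event$onset_ms < cfg$latency_min_ms) reasons <- c(reasons, "latency_low")
  if (event$onset_ms > cfg$latency_max_ms) reasons <- c(reasons, "latency_high")
  if (event$duration_ms < cfg$min_duration_ms) reasons <- c(reasons, "too_short")
  if (!has_fixation) reasons <- c(reasons, "no_fixation")
  if (event$edge) reasons <- c(reasons, "edge")
  event$accepted <- length(reasons) == 0
  event$rejection_reasons <- paste(reasons, collapse = ";")
  event
}

detect_eye <- function(traces, eye, cfg) {
  vel <- traces[[paste0("vel_", eye)]]
  acc <- traces[[paste0("acc_", eye)]]
  pos <- traces[[paste0("pos_", eye)]]
  valid_idx <- which(traces$valid_region)
  cand <- candidate_events(vel, cfg)
  if (nrow(cand) == 0) return(NULL)
  events <- lapply(seq_len(nrow(cand)), function(i) {
    pk <- cand$peak_index[i]
    s <- sign(cand$peak_velocity[i])
    # pre-event noise floor of the acceleration: zero is declared once the
    # signal falls back into the baseline noise band
    base <- acc[seq(min(valid_idx),
                    max(min(valid_idx) + 4, cand$run_start[i] - 3))]
    base <- base[!is.na(base)]
    tol <- if (length(base) >= 5)
      cfg$onset_accel_tol_mad * stats::mad(base, center = 0) else 0
    on <- locate_onset(acc, pk, s, cfg, valid_start = min(valid_idx),
                       zero_tol = tol)
    off <- locate_offset(vel, pk, s, cfg, valid_end = max(valid_idx))
    # the event's peak velocity is measured over the located event span:
    # a short noise run can anchor an event whose onset/offset embrace the
    # true saccade, whose peak must then be read from the full span
    span <- on$index:off$index
    pk_span <- span[which.max(abs(vel[span]))]
    ev <- data.frame(
      eye = eye,
      onset_ms = traces$t_ms[on$index],
      offset_ms = traces$t_ms[off$index],
      peak_time_ms = traces$t_ms[pk_span],
      peak_velocity_deg_s = abs(vel[pk_span]),
      amplitude_deg = abs(pos[off$index] - pos[on$index]),
      duration_ms = traces$t_ms[off$index] - traces$t_ms[on$index],
      direction = if (s < 0) "left" else "right",
      final_position_deg = pos[off$index],
      edge = on$edge || off$edge,
      stringsAsFactors = FALSE
    )
    fix_ok <- fixation_precedes(pos, on$index, 0, cfg,
                                valid_start = min(valid_idx))
    accept_saccade(ev, fix_ok, cfg)
  })
  do.call(rbind, events)
}

#' Detect the primary saccade of one trial
#'
#' Runs candidate detection, onset/offset localisation and the acceptance
#' gates independently for each eye, and marks the earliest accepted event
#' per eye as that eye's primary saccade. A trial with no accepted event on
#' either eye is inadequate.
#'
#' @param trial One interpolated trial's gaze rows.
#' @param cfg A [study_config()].
#' @param traces Optional precomputed [differentiate_trace()] output.
#' @return A data frame of all located events (possibly zero rows) with
#'   trial metadata, acceptance flags and a logical `primary` column.
#' @export
detect_trial <- function(trial, cfg = study_config(), traces = NULL) {
  if (is.null(traces)) traces <- differentiate_trace(trial, cfg)
  per_eye <- Filter(Negate(is.null),
                    lapply(c("left", "right"),
                           function(eye) detect_eye(traces, eye, cfg)))
  events <- if (length(per_eye) > 0) do.call(rbind, per_eye) else NULL
  meta <- trial[1, c("subject_id", "group", "task", "direction",
                     "eccentricity", "trial_index")]
  names(meta)[names(meta) == "direction"] <- "target_direction"
  if (is.null(events) || nrow(events) == 0) {
    out <- cbind(meta[0, ], data.frame(
      eye = character(0), onset_ms = numeric(0), offset_ms = numeric(0),
      peak_time_ms = numeric(0), peak_velocity_deg_s = numeric(0),
      amplitude_deg = numeric(0), duration_ms = numeric(0),
      direction = character(0), final_position_deg = numeric(0),
      edge = logical(0), accepted = logical(0),
      rejection_reasons = character(0), primary = logical(0)))
    return(out)
  }
  events$primary <- FALSE
  for (eye in c("left", "right")) {
    acc_idx <- which(events$eye == eye & events$accepted)
    if (length(acc_idx) > 0)
      events$primary[acc_idx[which.min(events$onset_ms[acc_idx])]] <- TRUE
  }
  cbind(meta[rep(1, nrow(events)), , drop = FALSE], events,
        row.names = NULL)
}

#' Detect saccades across a cohort
#'
#' @param gaze Interpolated gaze table (see [interpolate_cohort()]).
#' @param cfg A [study_config()].
#' @return A data frame of events over all trials (see [detect_trial()]).
#' @export
detect_cohort <- function(gaze, cfg = study_config()) {
  trials <- split_trials(gaze)
  out <- do.call(rbind, c(lapply(trials, detect_trial, cfg = cfg),
                          list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
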