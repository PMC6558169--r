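#' Analysis configuration for the saccade pipeline
#'
#' Collects every numeric threshold used by quality control, filtering,
#' saccade detection and metric computation. Defaults reproduce the published
#' processing rules: samples with validity code > 1 are missing; trials with
#' > 10\% missing, a > 100 ms contiguous gap, or > 80\% missing in the first
#' 50 ms are excluded; the first two trials per condition are practice; a
#' condition needs at least 9 surviving trials; saccades are detected where
#' velocity exceeds 50 deg/s on 2 consecutive samples, accepted with latency
#' in [100, 600] ms, duration >= 12 ms, and a stable preceding fixation
#' (< 1.5 deg from the cross, < 0.6 deg drift).
#'
#' @param sampling_rate_hz Nominal sampling rate of the tracker (Hz).
#' @param velocity_threshold_deg_s Saccade velocity threshold (deg/s).
#' @param consecutive_points Minimum consecutive supra-threshold samples.
#' @param sg_window Savitzky-Golay window length (odd number of samples).
#' @param sg_polyorder Savitzky-Golay polynomial order. Default 5: an
#'   11-point quintic fit recovers minimum-jerk peak velocity to within about
#'   1.5\% down to 5 deg amplitudes, where a cubic loses over 7\%.
#' @param onset_search_ms Backward search window for the saccade onset (ms
#'   before the velocity peak).
#' @param latency_min_ms,latency_max_ms Accepted latency window (ms,
#'   inclusive at both ends).
#' @param min_duration_ms Minimum accepted saccade duration (ms, inclusive).
#' @param fixation_radius_deg Maximum distance from the fixation cross during
#'   the pre-saccadic fixation (deg, strict).
#' @param fixation_drift_deg Maximum position range during fixation (deg,
#'   strict).
#' @param max_missing_frac Missing-fraction exclusion threshold (strict).
#' @param max_gap_ms Contiguous-gap exclusion threshold (ms, strict).
#' @param max_missing_first50_frac Early-window missing-fraction threshold
#'   (strict).
#' @param first50_ms Length of the early window (ms).
#' @param practice_trials Number of leading practice trials dropped per
#'   condition.
#' @param min_trials_per_condition Minimum surviving trials for a condition
#'   to be accepted.
#' @param viewing_distance_cm Eye-to-screen distance used for geometry
#'   conversions (cm).
#' @param ino_z_margin Margin added to the highest control Z-score to form
#'   the subclinical INO cutoff.
#' @param qc_eye_rule How the per-eye exclusion rules combine: `"any"`
#'   excludes the trial if either eye trips a rule, `"all"` only if both do.
#' @param di_aggregation `"mean_of_ratios"` (default) averages the per-trial
#'   abducting/adducting velocity ratio; `"ratio_of_means"` divides the mean
#'   abducting by the mean adducting peak velocity.
#' @param hc_z_leave_one_out If `TRUE`, each control's Z-score is computed
#'   against the other controls only.
#' @param offset_velocity_threshold_deg_s Velocity level treated as "zero"
#'   when locating the saccade offset (deg/s).
#' @param onset_accel_tol_mad Multiple of the pre-event acceleration noise
#'   floor (median absolute deviation about zero) below which the
#'   acceleration counts as "zero" during onset search. 0 reverts to an
#'   exact sign change; the default 1 makes the zero declaration robust to
#'   measurement noise while leaving noise-free data untouched.
#' @param analyze_vertical If `TRUE`, vertical traces are also filtered
#'   (detection remains horizontal).
#'
#' @return An object of class `study_config` (a validated named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$velocity_threshold_deg_s
study_config <- function(sampling_rate_hz = 300,
                         velocity_threshold_deg_s = 50,
                         consecutive_points = 2,
                         sg_window = 11,
                         sg_polyorder = 5,
                         onset_search_ms = 50,
                         latency_min_ms = 100,
                         latency_max_ms = 600,
                         min_duration_ms = 12,
                         fixation_radius_deg = 1.5,
                         fixation_drift_deg = 0.6,
                         max_missing_frac = 0.10,
                         max_gap_ms = 100,
                         max_missing_first50_frac = 0.80,
                         first50_ms = 50,
                         practice_trials = 2,
                         min_trials_per_condition = 9,
                         viewing_distance_cm = 60,
                         ino_z_margin = 2.0,
                         qc_eye_rule = c("any", "all"),
                         di_aggregation = c("mean_of_ratios", "ratio_of_means"),
                         hc_z_leave_one_out = FALSE,
                         offset_velocity_threshold_deg_s = 0,
                         onset_accel_tol_mad = 1,
                         analyze_vertical = FALSE) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    velocity_threshold_deg_s = velocity_threshold_deg_s,
    consecutive_points = consecutive_points,
    sg_window = sg_window,
    sg_polyorder = sg_polyorder,
    onset_search_ms = onset_search_ms,
    latency_min_ms = latency_min_ms,
    latency_max_ms = latency_max_ms,
    min_duration_ms = min_duration_ms,
    fixation_radius_deg = fixation_radius_deg,
    fixation_drift_deg = fixation_drift_deg,
    max_missing_frac = max_missing_frac,
    max_gap_ms = max_gap_ms,
    max_missing_first50_frac = max_missing_first50_frac,
    first50_ms = first50_ms,
    practice_trials = practice_trials,
    min_trials_per_condition = min_trials_per_condition,
    viewing_distance_cm = viewing_distance_cm,
    ino_z_margin = ino_z_margin,
    qc_eye_rule = match.arg(qc_eye_rule),
    di_aggregation = match.arg(di_aggregation),
    hc_z_leave_one_out = isTRUE(hc_z_leave_one_out),
    offset_velocity_threshold_deg_s = offset_velocity_threshold_deg_s,
    onset_accel_tol_mad = onset_accel_tol_mad,
    analyze_vertical = isTRUE(analyze_vertical)
  )
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  num <- c("sampling_rate_hz", "velocity_threshold_deg_s",
           "consecutive_points", "sg_window", "onset_search_ms",
           "latency_min_ms", "latency_max_ms", "min_duration_ms",
           "fixation_radius_deg", "fixation_drift_deg", "max_missing_frac",
           "max_gap_ms", "max_missing_first50_frac", "first50_ms",
           "min_trials_per_condition", "viewing_distance_cm", "ino_z_margin")
  for (k in num) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("config field '%s' must be a single positive number", k),
           call. = FALSE)
  }
  if (cfg$sg_window %% 2 != 1)
    stop("sg_window must be odd", call. = FALSE)
  if (cfg$sg_window < cfg$sg_polyorder + 2)
    stop("sg_window must be at least sg_polyorder + 2", call. = FALSE)
  if (cfg$latency_min_ms >= cfg$latency_max_ms)
    stop("latency_min_ms must be smaller than latency_max_ms", call. = FALSE)
  if (cfg$practice_trials < 0)
    stop("practice_trials must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Read and write pipeline configuration files
#'
#' Configuration files are flat YAML mappings; any key not present in the
#' file keeps its default from [study_config()]. Writing the default
#' configuration and reading it back is the identity.
#'
#' @param path Path to a YAML configuration file.
#' @param cfg A `study_config` object.
#' @return `read_config()` returns a `study_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  do.call(study_config, vals[intersect(names(vals), known)])
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (k in names(x)) cat(sprintf("  %-32s %s\n", k, format(x[[k]])))
  invisible(x)
}
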