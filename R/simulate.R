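#' Simulation configuration for synthetic saccade cohorts
#'
#' Defines the generative model for synthetic binocular pro-/anti-saccade
#' recordings: the task grid (4 conditions x 20 trials per task), per-task
#' latency distributions, the amplitude-duration main sequence, gain and
#' position-noise distributions, tracker dropout, anti-saccade direction
#' errors, and optional adduction slowing emulating internuclear
#' ophthalmoparesis (INO). All parameter defaults are stand-ins chosen for
#' realism; no recorded cohort underlies them.
#'
#' @param n_hc,n_ms Number of healthy-control and patient subjects.
#' @param tasks Tasks to simulate (`"prosaccade"`, `"antisaccade"`).
#' @param eccentricities Named vector of target eccentricities in degrees.
#' @param trials_per_condition Trials per (direction x eccentricity)
#'   condition and task.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param trial_duration_ms Recorded window after stimulus onset (ms).
#' @param latency_mean_ms,latency_sd_ms Named per-task latency mean/SD (ms).
#' @param latency_bounds_ms Truncation bounds of the latency distribution
#'   (ms); kept inside the 100-600 ms acceptance window so every simulated
#'   saccade is recoverable.
#' @param main_sequence_slope_ms_per_deg,main_sequence_intercept_ms
#'   Amplitude-duration law: duration = slope * amplitude + intercept.
#' @param gain_mean,gain_sd Saccade gain distribution (amplitude =
#'   gain * |target|).
#' @param noise_sd_deg SD of additive Gaussian position noise per eye (deg).
#' @param dropout_prob Stationary probability that a sample is lost
#'   (validity code 4 on both eyes).
#' @param dropout_burst_len Mean length of contiguous dropout bursts
#'   (samples).
#' @param antisaccade_error_prob Named per-group probability of a direction
#'   error in the anti-saccade task.
#' @param n_ms_ino Number of patient subjects given adduction slowing.
#' @param ino_adduction_factor Peak-velocity ratio adducting/abducting eye
#'   for affected subjects (1 = none; the adducting eye's waveform duration
#'   is stretched by 1/factor with amplitude preserved).
#' @param ino_directions Movement directions affected for those subjects.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_hc = 34, n_ms = 33,
                       tasks = c("prosaccade", "antisaccade"),
                       eccentricities = c(close = 9.2, far = 18.4),
                       trials_per_condition = 20,
                       sampling_rate_hz = 300,
                       trial_duration_ms = 1000,
                       latency_mean_ms = c(prosaccade = 195, antisaccade = 305),
                       latency_sd_ms = c(prosaccade = 25, antisaccade = 45),
                       latency_bounds_ms = c(110, 590),
                       main_sequence_slope_ms_per_deg = 2.2,
                       main_sequence_intercept_ms = 21,
                       gain_mean = 0.93, gain_sd = 0.05,
                       noise_sd_deg = 0.1,
                       dropout_prob = 0.02, dropout_burst_len = 3,
                       antisaccade_error_prob = c(HC = 0.20, MS = 0.36),
                       n_ms_ino = 0,
                       ino_adduction_factor = 0.7,
                       ino_directions = c("left", "right"),
                       seed = 1L) {
  cfg <- list(n_hc = n_hc, n_ms = n_ms, tasks = tasks,
              eccentricities = eccentricities,
              trials_per_condition = trials_per_condition,
              sampling_rate_hz = sampling_rate_hz,
              trial_duration_ms = trial_duration_ms,
              latency_mean_ms = latency_mean_ms,
              latency_sd_ms = latency_sd_ms,
              latency_bounds_ms = latency_bounds_ms,
              main_sequence_slope_ms_per_deg = main_sequence_slope_ms_per_deg,
              main_sequence_intercept_ms = main_sequence_intercept_ms,
              gain_mean = gain_mean, gain_sd = gain_sd,
              noise_sd_deg = noise_sd_deg,
              dropout_prob = dropout_prob,
              dropout_burst_len = dropout_burst_len,
              antisaccade_error_prob = antisaccade_error_prob,
              n_ms_ino = n_ms_ino,
              ino_adduction_factor = ino_adduction_factor,
              ino_directions = ino_directions,
              seed = seed)
  stopifnot(n_hc >= 0, n_ms >= 0, n_ms_ino <= n_ms,
            all(tasks %in% c("prosaccade", "antisaccade")),
            all(eccentricities > 0), trials_per_condition >= 1,
            gain_sd >= 0, noise_sd_deg >= 0,
            dropout_prob >= 0, dropout_prob <= 1, dropout_burst_len >= 1,
            all(antisaccade_error_prob >= 0 & antisaccade_error_prob <= 1),
            ino_adduction_factor > 0, ino_adduction_factor <= 1,
            latency_bounds_ms[1] < latency_bounds_ms[2])
  class(cfg) <- "sim_config"
  cfg
}

#' Minimum-jerk saccade waveform
#'
#' Position along a minimum-jerk trajectory of the given amplitude and
#' duration: 0 before movement onset, `amplitude` after the end, and
#' `A (10 tau^3 - 15 tau^4 + 6 tau^5)` with `tau = t / duration` in between.
#' The analytic peak velocity is `1.875 * amplitude / duration`, reached at
#' the movement midpoint.
#'
#' @param amplitude Movement amplitude (deg; may be signed).
#' @param duration Movement duration (same time unit as `t`; positive).
#' @param t Time from movement onset (vectorised).
#' @return Position at `t` (deg) for `minimum_jerk_position()`; velocity
#'   (deg per time unit) for `minimum_jerk_velocity()`.
#' @export
#' @examples
#' minimum_jerk_position(18.4, 60, 30)  # midpoint: 9.2
minimum_jerk_position <- function(amplitude, duration, t) {
  if (!is.numeric(duration) || any(duration <= 0))
    stop("duration must be positive", call. = FALSE)
  tau <- pmin(pmax(t / duration, 0), 1)
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @rdname minimum_jerk_position
#' @export
minimum_jerk_velocity <- function(amplitude, duration, t) {
  if (!is.numeric(duration) || any(duration <= 0))
    stop("duration must be positive", call. = FALSE)
  tau <- t / duration
  v <- amplitude / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Draw the stochastic description of one trial. Consumes the caller's RNG
# stream; sample construction is deferred to build_trial_samples() so that a
# trial can be rebuilt bit-for-bit from its truth row (see apply_ino()).
draw_trial_truth <- function(subject_id, group, task, direction, eccentricity,
                             trial_index, sim, ino_factor = 1) {
  target_deg <- ifelse(direction == "left", -1, 1) * eccentricity
  latency <- rtruncnorm1(1, sim$latency_mean_ms[[task]],
                         sim$latency_sd_ms[[task]],
                         sim$latency_bounds_ms[1], sim$latency_bounds_ms[2])
  gain <- max(0.1, stats::rnorm(1, sim$gain_mean, sim$gain_sd))
  amplitude <- gain * abs(target_deg)
  err <- task == "antisaccade" &&
    stats::runif(1) < sim$antisaccade_error_prob[[group]]
  move_sign <- if (task == "prosaccade") sign(target_deg)
               else if (err) sign(target_deg) else -sign(target_deg)
  saccade_direction <- if (move_sign < 0) "left" else "right"
  duration <- sim$main_sequence_slope_ms_per_deg * amplitude +
    sim$main_sequence_intercept_ms
  dur_l <- dur_r <- duration
  if (ino_factor < 1 && saccade_direction %in% sim$ino_directions) {
    # adduction = movement toward the nose: left eye on rightward saccades
    if (saccade_direction == "right") dur_l <- duration / ino_factor
    else dur_r <- duration / ino_factor
  }
  data.frame(
    subject_id = subject_id, group = group, task = task,
    direction = direction, eccentricity = eccentricity,
    trial_index = trial_index, target_deg = target_deg,
    saccade_direction = saccade_direction,
    correct_direction = !err,
    true_onset_ms = latency,
    true_gain = gain,
    true_amplitude_deg = amplitude,
    true_duration_ms_left = dur_l,
    true_duration_ms_right = dur_r,
    true_peak_velocity_deg_s_left = 1.875 * amplitude / dur_l * 1000,
    true_peak_velocity_deg_s_right = 1.875 * amplitude / dur_r * 1000,
    ino_factor = ino_factor,
    noise_seed = sample.int(.Machine$integer.max, 1),
    stringsAsFactors = FALSE
  )
}

# Deterministically realise the gaze samples of a truth row. Noise and
# dropout are drawn from a private RNG seeded by the trial's noise_seed, so
# the mapping truth -> samples is a pure function.
build_trial_samples <- function(truth, sim) {
  n <- round(sim$sampling_rate_hz * sim$trial_duration_ms / 1000)
  dt_ms <- 1000 / sim$sampling_rate_hz
  t_ms <- (seq_len(n) - 1) * dt_ms
  s <- ifelse(truth$saccade_direction == "left", -1, 1)
  xl <- s * minimum_jerk_position(truth$true_amplitude_deg,
                                  truth$true_duration_ms_left,
                                  t_ms - truth$true_onset_ms)
  xr <- s * minimum_jerk_position(truth$true_amplitude_deg,
                                  truth$true_duration_ms_right,
                                  t_ms - truth$true_onset_ms)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(truth$noise_seed)
  if (sim$noise_sd_deg > 0) {
    noise <- matrix(stats::rnorm(4 * n, 0, sim$noise_sd_deg), ncol = 4)
  } else {
    noise <- matrix(0, nrow = n, ncol = 4)
  }
  miss <- dropout_mask(n, sim$dropout_prob, sim$dropout_burst_len)
  if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old_seed, envir = globalenv())
  data.frame(
    subject_id = truth$subject_id, group = truth$group, task = truth$task,
    direction = truth$direction, eccentricity = truth$eccentricity,
    trial_index = truth$trial_index, t_ms = t_ms,
    x_left = xl + noise[, 1], y_left = noise[, 2],
    valid_left = ifelse(miss, 4L, 0L),
    x_right = xr + noise[, 3], y_right = noise[, 4],
    valid_right = ifelse(miss, 4L, 0L),
    stringsAsFactors = FALSE
  )
}

# Two-state (Gilbert) dropout chain: stationary missing probability exactly
# `prob`, mean burst length `burst_len` samples.
dropout_mask <- function(n, prob, burst_len) {
  if (prob <= 0) return(rep(FALSE, n))
  if (prob >= 1) return(rep(TRUE, n))
  p_exit <- 1 / burst_len                        # missing -> valid
  p_enter <- prob * p_exit / (1 - prob)          # valid -> missing
  p_enter <- min(p_enter, 1)
  miss <- logical(n)
  u <- stats::runif(n)
  miss[1] <- u[1] < prob
  for (i in seq_len(n)[-1]) {
    miss[i] <- if (miss[i - 1]) u[i] >= p_exit else u[i] < p_enter
  }
  miss
}

#' Simulate a single saccade trial
#'
#' Draws one trial's latency, gain, direction (with possible anti-saccade
#' direction error) and main-sequence duration from the simulation
#' configuration, then realises 300 Hz binocular samples with additive
#' Gaussian noise and tracker dropout. Both eyes are identical up to noise
#' unless adduction slowing is injected (`ino_factor < 1`).
#'
#' @param task `"prosaccade"` or `"antisaccade"`.
#' @param direction Target side, `"left"` or `"right"`.
#' @param eccentricity Target eccentricity (deg).
#' @param sim A [sim_config()].
#' @param subject_id,group,trial_index Trial metadata.
#' @param ino_factor Adduction peak-velocity factor for this subject
#'   (1 = unaffected).
#' @return A list with `samples` (gaze table rows) and `truth` (one-row
#'   ground-truth data frame).
#' @export
simulate_trial <- function(task, direction, eccentricity,
                           sim = sim_config(),
                           subject_id = "S01", group = "HC",
                           trial_index = 1L, ino_factor = 1) {
  stopifnot(task %in% c("prosaccade", "antisaccade"),
            direction %in% c("left", "right"))
  truth <- draw_trial_truth(subject_id, group, task, direction, eccentricity,
                            trial_index, sim, ino_factor)
  list(samples = build_trial_samples(truth, sim), truth = truth)
}

#' Inject adduction slowing into a simulated trial
#'
#' For saccades in the given direction, stretches the adducting eye's
#' waveform duration by `1 / factor` with amplitude preserved, so its true
#' peak velocity becomes `factor` times the abducting eye's. Samples are
#' rebuilt from the trial's stored noise seed, so `factor = 1` reproduces
#' the input bit for bit.
#'
#' @param trial A `list(samples, truth)` as returned by [simulate_trial()].
#' @param factor Adduction peak-velocity factor in (0, 1].
#' @param direction Movement direction affected (`"left"`, `"right"`, or
#'   both via `c("left", "right")`).
#' @param sim The [sim_config()] the trial was generated under.
#' @return A `list(samples, truth)` with the slowing applied.
#' @export
apply_ino <- function(trial, factor, direction, sim = sim_config()) {
  if (!is.numeric(factor) || factor <= 0 || factor > 1)
    stop("adduction factor must be in (0, 1]", call. = FALSE)
  truth <- trial$truth
  base_dur <- min(truth$true_duration_ms_left, truth$true_duration_ms_right)
  truth$true_duration_ms_left <- base_dur
  truth$true_duration_ms_right <- base_dur
  if (truth$saccade_direction %in% direction && factor < 1) {
    if (truth$saccade_direction == "right")
      truth$true_duration_ms_left <- base_dur / factor
    else
      truth$true_duration_ms_right <- base_dur / factor
  }
  truth$true_peak_velocity_deg_s_left <-
    1.875 * truth$true_amplitude_deg / truth$true_duration_ms_left * 1000
  truth$true_peak_velocity_deg_s_right <-
    1.875 * truth$true_amplitude_deg / truth$true_duration_ms_right * 1000
  truth$ino_factor <- ifelse(truth$saccade_direction %in% direction,
                             factor, 1)
  list(samples = build_trial_samples(truth, sim), truth = truth)
}

#' Mark tracker dropout in a trial
#'
#' Overwrites the validity codes of randomly chosen contiguous sample bursts
#' with code 4 on both eyes. The burst process is a two-state Markov chain
#' whose stationary missing probability equals `dropout_prob` and whose mean
#' burst length is `burst_len` samples.
#'
#' @param samples Gaze rows of one trial.
#' @param dropout_prob Stationary per-sample missing probability.
#' @param burst_len Mean burst length (samples).
#' @return The samples with updated validity codes.
#' @export
inject_missingness <- function(samples, dropout_prob, burst_len = 3) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, burst_len >= 1)
  miss <- dropout_mask(nrow(samples), dropout_prob, burst_len)
  samples$valid_left[miss] <- 4L
  samples$valid_right[miss] <- 4L
  samples
}

#' Simulate a synthetic pro-/anti-saccade cohort
#'
#' Generates the full task grid for every subject: per task, 2 directions x
#' `length(eccentricities)` eccentricities x `trials_per_condition` trials
#' (the default grid is 4 conditions x 20 trials, i.e. 160 trials per
#' subject over both tasks). The first `n_ms_ino` patient subjects receive
#' adduction slowing with `ino_adduction_factor`. The cohort is a pure
#' function of `(sim, seed)`.
#'
#' @param sim A [sim_config()].
#' @param seed Integer seed; defaults to `sim$seed`.
#' @return A list with `gaze` (sample table in the gaze CSV dialect) and
#'   `truth` (one ground-truth row per trial, including per-eye true
#'   durations and peak velocities and the subject's INO status).
#' @export
simulate_cohort <- function(sim = sim_config(), seed = sim$seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  subjects <- data.frame(
    subject_id = c(sprintf("HC%02d", seq_len(sim$n_hc)),
                   sprintf("MS%02d", seq_len(sim$n_ms))),
    group = c(rep("HC", sim$n_hc), rep("MS", sim$n_ms)),
    stringsAsFactors = FALSE
  )
  subjects$ino_factor <- 1
  if (sim$n_ms_ino > 0)
    subjects$ino_factor[subjects$group == "MS"][seq_len(sim$n_ms_ino)] <-
      sim$ino_adduction_factor

  grid <- expand.grid(trial_index = seq_len(sim$trials_per_condition),
                      eccentricity = unname(sim$eccentricities),
                      direction = c("left", "right"),
                      task = sim$tasks,
                      stringsAsFactors = FALSE)

  truth_rows <- vector("list", nrow(subjects) * nrow(grid))
  k <- 0
  for (i in seq_len(nrow(subjects))) {
    for (j in seq_len(nrow(grid))) {
      k <- k + 1
      truth_rows[[k]] <- draw_trial_truth(
        subjects$subject_id[i], subjects$group[i], grid$task[j],
        grid$direction[j], grid$eccentricity[j], grid$trial_index[j],
        sim, subjects$ino_factor[i])
    }
  }
  truth <- do.call(rbind, truth_rows)
  gaze <- do.call(rbind, lapply(seq_len(nrow(truth)), function(r)
    build_trial_samples(truth[r, ], sim)))
  rownames(truth) <- rownames(gaze) <- NULL
  list(gaze = gaze, truth = truth)
}
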