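# Shared fixtures and independent oracles, all built in code.

# Independent Savitzky-Golay oracle: explicit windowed least-squares
# polynomial fit via the normal equations; the deriv-th derivative of the
# fitted polynomial evaluated at the window centre.
polyfit_center_deriv <- function(y, polyorder, deriv, dt = 1) {
  w <- length(y)
  hw <- (w - 1) / 2
  z <- seq(-hw, hw)
  V <- outer(z, 0:polyorder, "^")
  coef <- solve(crossprod(V), crossprod(V, y))
  factorial(deriv) * coef[deriv + 1] / dt^deriv
}

# Minimal single-trial gaze table from a horizontal position vector
# (both eyes identical unless x_right given).
make_trial <- function(x, x_right = x, valid_left = 0L, valid_right = 0L,
                       sampling_rate_hz = 300, task = "prosaccade",
                       direction = "right", eccentricity = 18.4,
                       trial_index = 3L, subject_id = "S01", group = "HC") {
  n <- length(x)
  data.frame(
    subject_id = subject_id, group = group, task = task,
    direction = direction, eccentricity = eccentricity,
    trial_index = trial_index,
    t_ms = (seq_len(n) - 1) * 1000 / sampling_rate_hz,
    x_left = x, y_left = 0, valid_left = rep_len(valid_left, n),
    x_right = x_right, y_right = 0, valid_right = rep_len(valid_right, n),
    stringsAsFactors = FALSE
  )
}

# Noise-free minimum-jerk trial: saccade of amplitude A (deg, signed by
# direction) starting at onset_ms with main-sequence duration.
make_mj_trial <- function(A = 18.4, onset_ms = 200, duration_ms = NULL,
                          n = 300, sampling_rate_hz = 300,
                          direction = if (A >= 0) "right" else "left",
                          eccentricity = abs(A), ...) {
  if (is.null(duration_ms)) duration_ms <- 2.2 * abs(A) + 21
  t_ms <- (seq_len(n) - 1) * 1000 / sampling_rate_hz
  x <- sign(A) * minimum_jerk_position(abs(A), duration_ms, t_ms - onset_ms)
  make_trial(x, direction = direction, eccentricity = eccentricity, ...)
}

# Deterministic noiseless simulation settings (overridable).
sim_noise_free <- function(...) {
  args <- utils::modifyList(
    list(noise_sd_deg = 0, dropout_prob = 0, gain_sd = 0, gain_mean = 1),
    list(...))
  do.call(sim_config, args)
}
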