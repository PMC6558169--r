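#' Savitzky-Golay convolution kernel
#'
#' Central-point Savitzky-Golay coefficients: convolving a series with the
#' kernel equals fitting a least-squares polynomial of order `polyorder`
#' over each sliding window and evaluating its `deriv`-th derivative at the
#' window centre, scaled by `dt^-deriv`.
#'
#' @param window Odd window length (samples).
#' @param polyorder Polynomial order (< window).
#' @param deriv Derivative order: 0 (smoothing), 1 (velocity) or 2
#'   (acceleration).
#' @param dt Sample interval in the time unit of the desired derivative
#'   (seconds for deg/s and deg/s^2).
#' @return Numeric coefficient vector of length `window`.
#' @export
sg_kernel <- function(window, polyorder, deriv, dt = 1) {
  if (window %% 2 != 1 || window < 3)
    stop("window must be odd and >= 3", call. = FALSE)
  if (polyorder >= window)
    stop("polyorder must be smaller than window", call. = FALSE)
  if (!deriv %in% 0:2)
    stop("deriv must be 0, 1 or 2", call. = FALSE)
  if (deriv > polyorder)
    stop("deriv must not exceed polyorder", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("dt must be positive", call. = FALSE)
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = dt)
  as.numeric(F[(window + 1) / 2, ])
}

# Centered convolution with NA margins of half the window on each side.
apply_kernel <- function(x, kernel) {
  as.numeric(stats::filter(x, rev(kernel), method = "convolution", sides = 2))
}

#' Position, velocity and acceleration traces of a trial
#'
#' Smooths and differentiates the horizontal gaze channel of each eye with
#' Savitzky-Golay kernels of derivative order 0, 1 and 2 (window and
#' polynomial order from the configuration), yielding position (deg),
#' velocity (deg/s) and acceleration (deg/s^2) on the trial's time base.
#' The first and last `(window - 1) / 2` samples have no full filter window;
#' they are outside the valid region and returned as `NA`, never padded.
#'
#' @param trial One interpolated trial (no interior missing samples; see
#'   [interpolate_missing()]).
#' @param cfg A [study_config()].
#' @return A data frame with `t_ms`, per-eye `pos_`, `vel_`, `acc_` columns
#'   (and `posy_` if `analyze_vertical`), and a logical `valid_region`
#'   column.
#' @export
differentiate_trace <- function(trial, cfg = study_config()) {
  n <- nrow(trial)
  if (n < cfg$sg_window)
    stop("trial has fewer samples (", n, ") than the filter window (",
         cfg$sg_window, ")", call. = FALSE)
  dt_s <- 1 / cfg$sampling_rate_hz
  k0 <- sg_kernel(cfg$sg_window, cfg$sg_polyorder, 0, dt_s)
  k1 <- sg_kernel(cfg$sg_window, cfg$sg_polyorder, 1, dt_s)
  k2 <- sg_kernel(cfg$sg_window, cfg$sg_polyorder, 2, dt_s)
  hw <- (cfg$sg_window - 1) / 2
  valid <- seq_len(n) > hw & seq_len(n) <= n - hw
  out <- data.frame(t_ms = trial$t_ms, valid_region = valid)
  for (eye in c("left", "right")) {
    x <- trial[[paste0("x_", eye)]]
    out[[paste0("pos_", eye)]] <- apply_kernel(x, k0)
    out[[paste0("vel_", eye)]] <- apply_kernel(x, k1)
    out[[paste0("acc_", eye)]] <- apply_kernel(x, k2)
    if (cfg$analyze_vertical)
      out[[paste0("posy_", eye)]] <- apply_kernel(trial[[paste0("y_", eye)]], k0)
  }
  out
}
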