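#' Plot one trial's position and velocity traces with detected events
#'
#' Two stacked base-graphics panels: horizontal position and velocity of
#' both eyes, with the accepted primary saccade's onset and offset marked.
#'
#' @param trial One interpolated trial's gaze rows.
#' @param cfg A [study_config()].
#' @export
plot_trial <- function(trial, cfg = study_config()) {
  traces <- differentiate_trace(trial, cfg)
  events <- detect_trial(trial, cfg, traces)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(traces$t_ms, cbind(traces$pos_left, traces$pos_right),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "time (ms)", ylab = "position (deg)",
                    main = sprintf("%s %s %s %.1f deg trial %d",
                                   trial$subject_id[1], trial$task[1],
                                   trial$direction[1], trial$eccentricity[1],
                                   trial$trial_index[1]))
  graphics::legend("topleft", c("left eye", "right eye"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(traces$t_ms, cbind(traces$vel_left, traces$vel_right),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "time (ms)", ylab = "velocity (deg/s)")
  graphics::abline(h = c(-1, 1) * cfg$velocity_threshold_deg_s, lty = 3)
  prim <- events[events$primary, , drop = FALSE]
  if (nrow(prim) > 0)
    graphics::abline(v = c(prim$onset_ms, prim$offset_ms), lty = 2,
                     col = "grey40")
  invisible(events)
}

#' Strip plot of dysconjugacy Z-scores per direction
#'
#' Controls and patients side by side per direction, with the subclinical
#' INO cutoff (highest control Z + margin) drawn as a dashed line and
#' flagged subjects filled.
#'
#' @param ino Output of [ino_screen()].
#' @export
plot_di_z <- function(ino) {
  dirs <- unique(ino$direction)
  old <- graphics::par(mfrow = c(1, length(dirs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in dirs) {
    x <- ino[ino$direction == d & !is.na(ino$z_di), , drop = FALSE]
    g <- as.integer(factor(x$group, levels = c("HC", "MS")))
    graphics::plot(jitter(g, amount = 0.08), x$z_di, xlim = c(0.5, 2.5),
                   xaxt = "n", xlab = "", ylab = "Z (dysconjugacy index)",
                   main = paste(d, "direction"),
                   pch = ifelse(x$ino, 19, 1))
    graphics::axis(1, at = 1:2, labels = c("HC", "MS"))
    graphics::abline(h = x$cutoff[1], lty = 2)
  }
  invisible(NULL)
}
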