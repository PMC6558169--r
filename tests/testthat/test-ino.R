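make_binocular_events <- function(pv_left, pv_right, direction = "right",
                                  subject_id = "S1", group = "HC",
                                  task = "prosaccade", eccentricity = 18.4) {
  n <- length(pv_left)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = subject_id, group = group, task = task,
               target_direction = direction, eccentricity = eccentricity,
               trial_index = i + 2L,
               eye = c("left", "right"), onset_ms = 200, offset_ms = 260,
               peak_time_ms = 230,
               peak_velocity_deg_s = c(pv_left[i], pv_right[i]),
               amplitude_deg = 17, duration_ms = 60, direction = direction,
               final_position_deg = 17, edge = FALSE, accepted = TRUE,
               rejection_reasons = "", primary = TRUE,
               stringsAsFactors = FALSE)
  }))
}

test_that("equal binocular velocities give a dysconjugacy index of 1", {
  ev <- make_binocular_events(rep(400, 5), rep(400, 5))
  r <- dysconjugacy_index(ev, "right")
  expect_equal(r$di, 1.0)
  expect_equal(r$n_trials, 5)
})

test_that("the index is the abducting over adducting velocity ratio", {
  # rightward: right eye abducts; slowed left (adducting) eye at 0.7x
  ev <- make_binocular_events(rep(280, 4), rep(400, 4), direction = "right")
  expect_equal(dysconjugacy_index(ev, "right")$di, 400 / 280)
  # leftward: left eye abducts
  ev2 <- make_binocular_events(rep(400, 4), rep(280, 4), direction = "left")
  expect_equal(dysconjugacy_index(ev2, "left")$di, 400 / 280)
  # requesting the direction with no trials -> undefined flag
  expect_true(is.na(dysconjugacy_index(ev2, "right")$di))
  # ratio-of-means option agrees for constant velocities
  cfg2 <- study_config(di_aggregation = "ratio_of_means")
  expect_equal(dysconjugacy_index(ev, "right", cfg2)$di, 400 / 280)
})

test_that("only binocular far-condition prosaccade trials enter the index", {
  ev <- make_binocular_events(rep(300, 3), rep(300, 3))
  close_ev <- make_binocular_events(rep(100, 3), rep(400, 3),
                                    eccentricity = 9.2)
  anti_ev <- make_binocular_events(rep(100, 3), rep(400, 3),
                                   task = "antisaccade")
  mono <- make_binocular_events(100, 400)
  mono <- mono[mono$eye == "right", ]       # right eye only
  mono$trial_index <- 99L
  all_ev <- rbind(ev, close_ev, anti_ev, mono)
  r <- dysconjugacy_index(all_ev, "right")
  expect_equal(r$di, 1.0)
  expect_equal(r$n_trials, 3)
})

test_that("Z-scores follow the control mean and sample SD", {
  expect_equal(z_scores(1.3, c(1.0, 1.1, 1.2)), 2.0)   # sample SD = 0.1
  expect_equal(z_scores(1.1, c(1.0, 1.1, 1.2)), 0.0)
  expect_error(z_scores(1.2, 1.0), "at least 2")
  expect_error(z_scores(1.2, c(1.0, 1.0)), "degenerate")
  # invariance under common affine rescaling of all indices
  set.seed(21)
  hc <- rnorm(20, 1, 0.05); ms <- rnorm(5, 1.2, 0.05)
  for (i in 1:5) {
    a <- runif(1, 0.5, 3); b <- runif(1, -1, 1)
    expect_equal(z_scores(a * ms + b, a * hc + b), z_scores(ms, hc),
                 tolerance = 1e-10)
  }
})

test_that("the INO cutoff is the highest control Z plus the margin, strict", {
  expect_equal(ino_cutoff(c(0.3, 1.7, -0.5)), 3.7)
  expect_error(ino_cutoff(numeric(0)), "no control")
  di <- data.frame(subject_id = c(sprintf("HC%d", 1:5), "MS1", "MS2"),
                   group = c(rep("HC", 5), "MS", "MS"),
                   direction = "right",
                   di = c(1.00, 1.02, 0.98, 1.01, 0.99, NA, NA),
                   n_trials = 10)
  # MS1 exactly at the cutoff must not be flagged; MS2 above it must be
  hc_z <- z_scores(di$di[1:5], di$di[1:5])
  cut <- ino_cutoff(hc_z, 2)
  sd_hc <- sd(di$di[1:5]); mu <- mean(di$di[1:5])
  di$di[6] <- mu + (cut - 1e-6) * sd_hc   # Z at (not above) the cutoff
  di$di[7] <- mu + (cut + 0.01) * sd_hc   # Z > cutoff
  scr <- ino_screen(di)
  expect_false(scr$ino[scr$subject_id == "MS1"])
  expect_true(scr$ino[scr$subject_id == "MS2"])
  expect_false(any(scr$ino[scr$group == "HC"]))
})

test_that("DI recovery decreases monotonically with the adduction factor", {
  dis <- sapply(c(1.0, 0.85, 0.7), function(f) {
    sim <- sim_noise_free(n_hc = 0, n_ms = 1, n_ms_ino = 1,
                          ino_adduction_factor = f, tasks = "prosaccade",
                          trials_per_condition = 6)
    coh <- simulate_cohort(sim, seed = 17)
    qc <- qc_cohort(coh$gaze)
    clean <- drop_practice(interpolate_cohort(coh$gaze, qc))
    ev <- detect_cohort(clean)
    mean(c(dysconjugacy_index(ev, "left")$di,
           dysconjugacy_index(ev, "right")$di))
  })
  expect_equal(dis[1], 1.0, tolerance = 0.02)  # factor 1: DI within 2% of 1
  expect_true(dis[3] > dis[2] && dis[2] > dis[1])
  expect_equal(dis[3], 1 / 0.7, tolerance = 0.05)
})
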