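test_that("candidates require two consecutive supra-threshold samples", {
  cfg <- study_config()
  expect_equal(nrow(candidate_events(rep(0, 100), cfg)), 0)
  v <- rep(0, 100); v[50] <- 80               # isolated sample
  expect_equal(nrow(candidate_events(v, cfg)), 0)
  v[51] <- 90                                  # two consecutive
  cand <- candidate_events(v, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$peak_index, 51)
  expect_equal(cand$peak_velocity, 90)
  # two runs separated by a sub-threshold sample are distinct candidates
  v2 <- rep(0, 100); v2[20:25] <- 100; v2[40:45] <- -120
  cand2 <- candidate_events(v2, cfg)
  expect_equal(nrow(cand2), 2)
  expect_equal(sign(cand2$peak_velocity), c(1, -1))
})

test_that("detection recovers the candidate at the analytic peak", {
  tr <- make_mj_trial(A = 18.4, onset_ms = 200)
  tc <- differentiate_trace(tr)
  cand <- candidate_events(tc$vel_left)
  expect_equal(nrow(cand), 1)
  t_peak_true <- 200 + (2.2 * 18.4 + 21) / 2   # midpoint of the movement
  expect_lt(abs(tc$t_ms[cand$peak_index] - t_peak_true), 1000 / 300 + 1e-9)
})

test_that("onset falls back to the acceleration minimum when no zero exists", {
  acc <- seq(5, 100, length.out = 50)          # strictly positive window
  res <- locate_onset(acc, peak_index = 40, move_sign = 1,
                      valid_start = 1L)
  win <- (40 - 15):39
  expect_equal(res$index, win[which.min(abs(acc[win]))])
  expect_false(res$edge)
  # window truncated by the valid region -> edge flag
  res2 <- locate_onset(acc, peak_index = 10, move_sign = 1, valid_start = 6L)
  expect_true(res2$edge)
})

test_that("offset is the first at-or-below-zero crossing after the peak", {
  v <- c(rep(0, 10), 100, 200, 100, 0, -5, 0)
  res <- locate_offset(v, peak_index = 12, move_sign = 1)
  expect_equal(res$index, 14)                  # exact zero sample
  expect_false(res$edge)
  v2 <- c(rep(0, 10), seq(60, 200, length.out = 10))  # never returns
  res2 <- locate_offset(v2, peak_index = 15, move_sign = 1)
  expect_true(res2$edge)
})

test_that("fixation gating uses strict distance and drift bounds", {
  cfg <- study_config()
  expect_true(fixation_precedes(rep(0, 60), 50, 0, cfg))
  pos <- rep(0, 60); pos[20] <- 1.6            # beyond 1.5 deg
  expect_false(fixation_precedes(pos, 50, 0, cfg))
  drift <- seq(0, 0.6, length.out = 49)        # range exactly 0.6: strict
  expect_false(fixation_precedes(c(drift, rep(0.6, 11)), 50, 0, cfg))
  drift_ok <- seq(0, 0.59, length.out = 49)
  expect_true(fixation_precedes(c(drift_ok, rep(10, 11)), 50, 0, cfg))
  expect_false(fixation_precedes(rep(0, 60), 1, 0, cfg))  # empty window
})

test_that("every acceptance gate is independently triggerable", {
  base <- data.frame(onset_ms = 200, duration_ms = 50, edge = FALSE)
  ok <- accept_saccade(base, has_fixation = TRUE)
  expect_true(ok$accepted)
  expect_equal(ok$rejection_reasons, "")

  low <- base; low$onset_ms <- 90
  expect_equal(accept_saccade(low, TRUE)$rejection_reasons, "latency_low")
  high <- base; high$onset_ms <- 601
  expect_equal(accept_saccade(high, TRUE)$rejection_reasons, "latency_high")
  short <- base; short$duration_ms <- 11
  expect_equal(accept_saccade(short, TRUE)$rejection_reasons, "too_short")
  expect_equal(accept_saccade(base, FALSE)$rejection_reasons, "no_fixation")
  edge <- base; edge$edge <- TRUE
  expect_equal(accept_saccade(edge, TRUE)$rejection_reasons, "edge")

  # inclusive boundaries: latency 100 and 600 ms, duration exactly 12 ms
  for (onset in c(100, 600)) {
    b <- base; b$onset_ms <- onset
    expect_true(accept_saccade(b, TRUE)$accepted)
  }
  b <- base; b$duration_ms <- 12
  expect_true(accept_saccade(b, TRUE)$accepted)
})

test_that("the primary saccade is the earliest accepted event per eye", {
  # two saccades in one trial: 150 ms and 500 ms
  t_ms <- (0:299) * 1000 / 300
  x <- minimum_jerk_position(9.2, 2.2 * 9.2 + 21, t_ms - 150) +
    minimum_jerk_position(9.2, 2.2 * 9.2 + 21, t_ms - 500)
  tr <- make_trial(x, eccentricity = 18.4)
  ev <- detect_trial(tr)
  prim <- ev[ev$primary & ev$eye == "left", ]
  expect_equal(nrow(prim), 1)
  expect_lt(abs(prim$onset_ms - 150), 10)
  expect_equal(sum(ev$eye == "left"), 2)

  # flat trace: no candidates, trial inadequate
  ev0 <- detect_trial(make_trial(rep(0, 300)))
  expect_equal(nrow(ev0), 0)
})

test_that("detection is equivariant under time shifts and mirroring", {
  base_onset <- 200
  tr <- make_mj_trial(A = 12, onset_ms = base_onset)
  ev <- detect_trial(tr)
  prim <- ev[ev$primary & ev$eye == "left", ]

  for (shift_ms in c(-60, 100)) {
    tr2 <- make_mj_trial(A = 12, onset_ms = base_onset + shift_ms)
    p2 <- detect_trial(tr2)
    p2 <- p2[p2$primary & p2$eye == "left", ]
    expect_equal(p2$onset_ms - prim$onset_ms, shift_ms, tolerance = 1e-9)
    expect_equal(p2$peak_velocity_deg_s, prim$peak_velocity_deg_s,
                 tolerance = 1e-9)
  }

  mir <- make_mj_trial(A = -12, onset_ms = base_onset, direction = "left")
  pm <- detect_trial(mir)
  pm <- pm[pm$primary & pm$eye == "left", ]
  expect_equal(pm$onset_ms, prim$onset_ms)
  expect_equal(pm$peak_velocity_deg_s, prim$peak_velocity_deg_s,
               tolerance = 1e-9)
  expect_equal(pm$direction, "left")
})
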