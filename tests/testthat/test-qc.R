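test_that("missing mask follows the validity-code rule", {
  tr <- make_trial(rep(0, 4), valid_left = c(0L, 1L, 2L, 4L))
  expect_equal(missing_mask(tr, "left"), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(missing_mask(tr, "right"), rep(FALSE, 4))
  expect_length(missing_mask(tr[0, ], "left"), 0)
})

test_that("each exclusion rule trips on its own fixture and not on a clean trial", {
  mk <- function(valid) make_trial(rep(0, 300), valid_left = valid)

  # 31 of 300 scattered missing samples: 10.33% > 10%, gaps short
  v <- rep(0L, 300); v[seq(20, 290, by = 9)][1:31] <- 4L
  r1 <- exclusion_decision(mk(v))
  expect_true(r1$excluded)
  expect_equal(r1$reasons, "frac_gt_10")
  expect_equal(r1$missing_fraction_left, 31 / 300)

  # exactly 30 of 300 (10.0%) scattered: boundary retained, not "more than"
  v <- rep(0L, 300); v[seq(20, 290, by = 9)][1:30] <- 4L
  r2 <- exclusion_decision(mk(v))
  expect_false(r2$excluded)

  # contiguous run of 31 samples = 103.3 ms > 100 ms (also 10.33% overall,
  # so the fraction rule fires alongside; a 31-sample run in a 300-sample
  # trial necessarily exceeds 10%)
  v <- rep(0L, 300); v[100:130] <- 4L
  r3 <- exclusion_decision(mk(v))
  expect_true(r3$excluded)
  expect_equal(r3$reasons, "frac_gt_10;gap_gt_100ms")
  expect_equal(r3$longest_gap_ms_left, 31 * 1000 / 300)

  # a 31-sample run alone (7.75% of a 400-sample record) fires only the gap
  v <- rep(0L, 400); v[100:130] <- 4L
  r3b <- exclusion_decision(make_trial(rep(0, 400), valid_left = v))
  expect_equal(r3b$reasons, "gap_gt_100ms")

  # a 30-sample run is exactly 100 ms: strict rule does not fire
  v <- rep(0L, 400); v[100:129] <- 4L
  expect_false(exclusion_decision(make_trial(rep(0, 400), valid_left = v))$excluded)

  # 13 of the 15 samples in [0, 50) ms missing: 86.7% > 80%
  v <- rep(0L, 300); v[1:13] <- 4L
  r4 <- exclusion_decision(mk(v))
  expect_true(r4$excluded)
  expect_equal(r4$reasons, "first50_gt_80")
  expect_equal(r4$missing_first50_fraction_left, 13 / 15)

  # clean trial
  r5 <- exclusion_decision(mk(rep(0L, 300)))
  expect_false(r5$excluded)
  expect_equal(r5$reasons, "")
})

test_that("eye-combination rule and manual exclusions behave as configured", {
  v <- rep(0L, 300); v[1:40] <- 4L
  tr <- make_trial(rep(0, 300), valid_left = v)   # right eye clean
  expect_true(exclusion_decision(tr, study_config())$excluded)
  expect_false(
    exclusion_decision(tr, study_config(qc_eye_rule = "all"))$excluded)

  rep_manual <- qc_cohort(tr, manual_exclusions = tr[1, ])
  expect_true(rep_manual$excluded)
  expect_true(grepl("manual", rep_manual$reasons))
})

test_that("exclusion is monotone in added missingness", {
  set.seed(8)
  for (i in 1:20) {
    v <- ifelse(runif(300) < 0.08, 4L, 0L)
    tr <- make_trial(rep(0, 300), valid_left = v)
    before <- exclusion_decision(tr)$excluded
    extra <- v
    extra[sample(which(extra == 0L), 20)] <- 4L
    after <- exclusion_decision(make_trial(rep(0, 300),
                                           valid_left = extra))$excluded
    expect_true(!before || after)
  }
})

test_that("interpolation fills gaps linearly and never alters valid samples", {
  x <- c(1, NA_real_, 3); x[2] <- 99  # recorded value at missing sample
  tr <- make_trial(c(1, 99, 3), valid_left = c(0L, 4L, 0L))
  out <- interpolate_missing(tr)
  expect_equal(out$x_left, c(1, 2, 3))
  expect_equal(out$interp_left, c(FALSE, TRUE, FALSE))

  tr2 <- make_trial(c(0, 9, 9, 9, 4), valid_left = c(0L, 4L, 4L, 4L, 0L))
  expect_equal(interpolate_missing(tr2)$x_left, c(0, 1, 2, 3, 4))

  clean <- make_trial(rnorm(20))
  expect_equal(interpolate_missing(clean)$x_left, clean$x_left)

  # leading/trailing runs take the nearest valid value
  tr3 <- make_trial(c(9, 5, 9), valid_left = c(4L, 0L, 4L))
  expect_equal(interpolate_missing(tr3)$x_left, c(5, 5, 5))

  all_bad <- make_trial(rep(0, 10), valid_left = 4L)
  expect_error(interpolate_missing(all_bad), "no valid samples")

  # property: valid samples pass through untouched
  set.seed(9)
  for (i in 1:10) {
    v <- ifelse(runif(50) < 0.2, 4L, 0L)
    if (all(v == 4L)) v[1] <- 0L
    tr <- make_trial(rnorm(50), valid_left = v)
    out <- interpolate_missing(tr)
    expect_equal(out$x_left[v <= 1], tr$x_left[v <= 1])
    expect_true(all(is.finite(out$x_left)))
  }
})

test_that("practice trials are dropped and condition acceptance is >= 9", {
  sim <- sim_config(n_hc = 1, n_ms = 0, tasks = "prosaccade",
                    trials_per_condition = 20)
  gaze <- simulate_cohort(sim, seed = 11)$gaze
  kept <- drop_practice(gaze)
  expect_equal(sort(unique(kept$trial_index)), 3:20)

  two <- gaze[gaze$trial_index <= 2, ]
  expect_equal(nrow(drop_practice(two)), 0)
  odd <- gaze[gaze$trial_index %in% c(5, 7), ]
  expect_equal(nrow(drop_practice(odd)), nrow(odd))

  expect_true(accept_condition(9))
  expect_false(accept_condition(8))
  expect_true(accept_condition(18))
})
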