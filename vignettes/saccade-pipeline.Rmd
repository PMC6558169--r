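---
title: "From binocular gaze samples to saccade metrics and INO screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binocular gaze samples to saccade metrics and INO screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadepipe)
```

## The measurement problem

In a pro-/anti-saccade experiment a subject fixates a central cross; the
cross jumps to the periphery (here 9.2 or 18.4 degrees left or right, 20
trials per condition and task) and the subject looks toward it
(prosaccade) or to its mirror position (anti-saccade). A video eye tracker
records both eyes' gaze at 300 Hz for 1 s from each target jump, with an
integer validity code per eye and sample. From these traces the pipeline
derives latency, peak velocity, amplitude, duration and gain of the primary
saccade, anti-saccade direction-error performance, and a binocular
*dysconjugacy index* (DI): the ratio of abducting-eye to adducting-eye peak
velocity for large saccades, computed per movement direction. Slowed
adduction — the signature of internuclear ophthalmoparesis (INO), caused by
damage to the medial longitudinal fasciculus and clinically relevant in
multiple sclerosis — inflates the DI even when no deficit is visible at the
bedside. Standardising a subject's DI against the healthy-control
distribution,

$$Z_{DI} = \frac{DI - \overline{DI}_{HC}}{SD(DI_{HC})},$$

and flagging values above the highest control Z plus a margin of 2 yields a
conservative screen for subclinical INO.

Because raw recordings of this kind are rarely shared, the package pairs
the analysis chain with a synthetic cohort generator that produces
binocular recordings with full per-trial ground truth, so every stage can
be validated by parameter recovery rather than by eyeball.

## Quality control

A sample is unusable when its validity code exceeds 1. Three per-trial
exclusion rules are applied per eye, each a *strict* inequality ("more
than"), and a trial is excluded when either eye trips any rule
(`qc_eye_rule = "any"`; the combination is configurable because the
original procedure does not state it):

* more than 10% of samples missing;
* more than 100 ms missing contiguously — run length times the nominal
  sample interval (timestamps are ignored here so that clock jitter cannot
  flip the decision);
* more than 80% missing in the first 50 ms.

Note an arithmetic coupling at 300 Hz and 1 s trials: the shortest run
exceeding 100 ms is 31 samples, which is already 10.33% of 300, so the gap
rule can never fire alone on a full-length trial; both reasons are then
reported. Surviving trials have interior missing runs replaced by linear
interpolation between the nearest valid neighbours; leading/trailing runs
take the nearest valid value, and every filled sample is flagged in
`interp_left`/`interp_right` so provenance stays auditable. The first two
trials of every condition are practice and dropped; a condition counts only
if at least 9 trials (half of the 18 analysable ones) survive all stages.
Visual inspection of position-time diagrams is represented by an explicit
manual-exclusion list (`reason = "manual"`), not by an automatic surrogate.

## Kinematics

Position, velocity and acceleration are obtained with an 11-point sliding
Savitzky-Golay filter at derivative orders 0, 1 and 2: each output sample
equals the chosen derivative of a least-squares polynomial fitted over the
centred window, so polynomials up to the fit order pass through unchanged.
The first and last five samples have no full window; they are reported as
`NA` and excluded from the valid region rather than padded, so no
kinematics are fabricated near trial boundaries.

The polynomial order is a genuine design choice: the source procedure
fixes only the window (11 points) and the derivative orders. We default to
a quintic fit (`sg_polyorder = 5`). A cubic over 36.7 ms strongly flattens
the narrow velocity peak of small saccades, as the chunk below
demonstrates on a noise-free minimum-jerk saccade; the quintic keeps the
peak-velocity error within the 5% recovery bound our validation suite
asserts down to 5-degree amplitudes, while still attenuating white position
noise:

```{r polyorder, eval = FALSE}
pv_error <- function(polyorder, A = 5) {
  cfg <- study_config(sg_polyorder = polyorder)
  D <- 2.2 * A + 21
  t_ms <- (0:299) * 1000 / 300
  x <- minimum_jerk_position(A, D, t_ms - 200)
  tr <- data.frame(subject_id = "S", group = "HC", task = "prosaccade",
                   direction = "right", eccentricity = A, trial_index = 3,
                   t_ms = t_ms, x_left = x, y_left = 0, valid_left = 0L,
                   x_right = x, y_right = 0, valid_right = 0L)
  pv <- max(abs(differentiate_trace(tr, cfg)$vel_left), na.rm = TRUE)
  pv / (1.875 * A / D * 1000) - 1
}
sapply(c(cubic = 3, quintic = 5), pv_error)
```

## Saccade detection

Detection runs independently per eye on the horizontal channel:

1. **Candidates.** Every maximal run with |velocity| > 50 deg/s over at
   least 2 consecutive samples yields one candidate, anchored at the run's
   absolute-velocity maximum — one candidate per run prevents a single
   saccade from being counted twice.
2. **Onset.** Searching backward from the velocity peak within 50 ms, the
   onset is the sample after the acceleration (signed in the movement
   direction) last returned to zero; if it never does, the sample of
   minimum |acceleration| in the window is the fallback. On noisy traces an
   *exact* zero test fires inside the baseline noise band and marks onsets
   early; zero is therefore declared when the acceleration falls below the
   pre-event noise floor, estimated as the median absolute deviation (about
   zero) of the baseline acceleration times `onset_accel_tol_mad`
   (default 1). This adaptive, median-based noise scale is standard
   practice in saccade detection; for noise-free data the floor is exactly
   zero and the rule reduces to the plain sign change. With it, the mean
   latency error on simulated noisy cohorts stays within the 4 ms bound
   asserted by the validation suite.
3. **Offset.** The first sample after the peak where the direction-signed
   velocity is at or below zero (`offset_velocity_threshold_deg_s`,
   default 0 — an exact zero is rarely sampled, so the crossing is used).
   The event's peak velocity and peak time are then measured over the
   located onset-offset span: a short noise run can anchor an event whose
   bounds embrace the true saccade, and the span maximum, not the run
   maximum, is the saccade's peak.
4. **Acceptance.** An event is a saccade if its latency lies in
   [100, 600] ms (inclusive at both ends; the source wording does not
   resolve inclusivity, and the inclusive reading is configurable), its
   duration is at least 12 ms, a fixation precedes it — every pre-onset
   sample within 1.5 degrees of the cross and a position range below
   0.6 degrees, both strict — and neither the onset search window nor the
   offset ran off the valid filter region (`edge`). All failed gates are
   recorded, so every rejection is attributable.

The earliest accepted event per eye is the trial's primary saccade; a trial
with none on either eye is inadequate.

## Metrics and the dysconjugacy index

Gain is the final eye position over the target position; for anti-saccades
the reference is the *mirror* of the target (the correct landing point),
a convention that is configurable because the source defines anti-saccade
gain only as "determined similarly". An anti-saccade is correct when the
primary saccade heads away from the target side; performance is the
percentage of correct among adequate anti-saccade trials. Task-difference
variables are `latency_difference` (anti minus pro) and
`peak_velocity_difference` (pro minus anti), plus a scaled variant that
divides each trial's peak velocity by its amplitude before averaging,
removing the main-sequence dependence of velocity on saccade size.

The DI uses prosaccade trials of the far (18.4 degree) condition whose
primary saccade was accepted in *both* eyes in the same trial (an
assumption the source leaves open). Per trial the abducting-over-adducting
peak-velocity ratio is formed and the subject's DI per direction is the
mean of the ratios; the mean-of-ratios is the default because it weighs
every trial equally under unbalanced trial counts, with ratio-of-means as a
config option. Z-scores follow the equation above with the sample SD of the
controls; controls are standardised against the full control distribution
including themselves (so the cutoff rule has control Z-values to work
with), with leave-one-out as an option. The cutoff is computed per
direction; a subject can thus be flagged in one direction only, matching
the clinical picture of unilateral INO.

## The synthetic cohort

The generator emulates the study design rather than any particular
recording: per subject and task, 4 conditions x 20 trials at 300 Hz over
1 s windows. Its defaults are the generative study conditions:

* **Waveform:** minimum-jerk position profile — smooth, with the analytic
  peak velocity $1.875\,A/D$ that all recovery tests use as ground truth.
* **Main sequence:** duration $D = 2.2\,A + 21$ ms, textbook values for
  human saccades.
* **Latency:** per-task normal distributions (195 ± 25 ms prosaccade,
  305 ± 45 ms anti-saccade) truncated to [110, 590] ms so that every
  generated event is recoverable inside the 100-600 ms acceptance window.
* **Gain:** normal with mean 0.93, SD 0.05 (mild physiological
  hypometria); amplitude = gain x |target|.
* **Noise:** additive white Gaussian position noise, SD 0.1 degrees per
  eye, a typical video-tracker precision figure.
* **Dropout:** a two-state Markov chain whose stationary missing
  probability is exactly `dropout_prob` (default 0.02) with mean burst
  length 3 samples — contiguous bursts like real tracking losses, and an
  unbiased rate so Monte-Carlo rate checks are exact.
* **Direction errors:** anti-saccade trials go toward the target with
  probability 0.20 (controls) / 0.36 (patients), giving cohort performance
  near 80% and 64%.
* **INO:** for affected subjects the adducting eye's waveform duration is
  stretched by 1/factor with amplitude preserved, so the true adducting
  peak velocity is exactly `factor` times the abducting one (default
  factor 0.7) — the precise abnormality the DI is built to detect.

Pre-stimulus fixation is not simulated as samples (acquisition starts at
the target jump); fixation checks therefore operate on the pre-saccadic
post-onset samples. Each trial's samples are a pure function of its
ground-truth row and a stored noise seed, which is what makes
`apply_ino(factor = 1)` a bitwise identity and the whole cohort
reproducible from `(sim_config, seed)`.

What the generator does *not* emulate — blinks as physiological events
(only validity-code dropout), smooth pursuit, vergence, head movement,
calibration drift, pink/drift noise, corrective saccades, and any
main-sequence curvature beyond the linear law. Green recovery tests
therefore certify the pipeline's correctness *given* these idealisations;
they do not certify behaviour on pathological real-world traces outside
them.

## Numerical choices and degenerate inputs

* All QC thresholds are strict inequalities; boundary trials (exactly 10%
  missing, exactly 100 ms gap, exactly 80% early missing) are retained.
* Latency bounds inclusive, duration bound inclusive ("at least").
* A velocity run must be at least `consecutive_points` (2) samples.
* `z_scores()` refuses fewer than 2 controls or a zero control SD;
  `ino_screen()` is skipped by `run_pipeline()` when any direction has
  fewer than 2 control DI values. An all-noise control cohort without
  position noise is exactly such a degenerate case: with identical eyes
  every control DI is 1 and the Z-score is undefined, which is why
  classification experiments need the default measurement noise while pure
  DI-recovery checks can run noise-free.
* Undefined quantities (no adequate trials, missing task, no binocular far
  trials) are emitted as flagged `NA`, never dropped silently.
* Validation problem sizes were chosen so that Monte-Carlo standard errors
  are small against the asserted bounds: ~1,000 trials for latency and
  error-rate distribution checks, a 30 + 30 subject cohort (10 affected)
  for the classification experiment, 100 random signals for the filter
  oracle, 25 randomised amplitudes for noise-free end-to-end recovery.

## Known limitations

* Horizontal-channel analysis only; vertical traces are carried through
  I/O (and optionally filtered) but never enter detection.
* One primary saccade per trial; corrective saccades are neither measured
  nor modelled.
* The onset rule inherits an irreducible sub-sample ambiguity: at 300 Hz
  the acceleration zero generally falls between samples, so single-trial
  latencies carry up to ~2 samples of quantisation error even noise-free.
* Group-level inference (mixed models, correlations with imaging) is out
  of scope; the pipeline emits tidy per-subject tables that such analyses
  would consume.
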