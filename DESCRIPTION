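Package: saccadepipe
Title: Binocular Pro-/Anti-Saccade Analysis and Subclinical INO Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes binocular gaze recordings from pro- and anti-saccade
    tasks into trial-level and subject-level oculomotor metrics. Implements
    missing-data quality control with linear interpolation, Savitzky-Golay
    smoothing and differentiation of gaze traces, velocity-threshold saccade
    detection with fixation and latency acceptance gates, latency / peak
    velocity / amplitude / duration / gain metrics, anti-saccade performance,
    and a binocular dysconjugacy index with Z-score screening for subclinical
    internuclear ophthalmoparesis. Includes a synthetic cohort generator with
    minimum-jerk saccade waveforms and per-trial ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
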