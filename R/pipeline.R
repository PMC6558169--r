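#' Run the full saccade analysis pipeline
#'
#' Chains all stages on a raw gaze table: quality control (missing-data
#' exclusion rules), interpolation of surviving trials, practice-trial
#' removal, Savitzky-Golay differentiation, saccade detection with
#' acceptance gates, per-trial metrics, per-subject summaries (including
#' anti-saccade performance and task differences), and dysconjugacy-index
#' INO screening when both groups are present.
#'
#' @param gaze A gaze sample table (see [read_gaze_table()]).
#' @param cfg A [study_config()].
#' @param manual_exclusions Optional manual exclusion list (see
#'   [qc_cohort()]).
#' @return A list of class `saccade_pipeline` with elements `qc`, `events`,
#'   `metrics`, `summary`, `cohort`, `subjects` (performance and task
#'   differences per subject) and `ino` (`NULL` without controls).
#' @export
run_pipeline <- function(gaze, cfg = study_config(),
                         manual_exclusions = NULL) {
  qc <- qc_cohort(gaze, cfg, manual_exclusions)
  clean <- interpolate_cohort(gaze, qc)
  clean <- drop_practice(clean, cfg)
  events <- detect_cohort(clean, cfg)
  metrics <- trial_metrics(events)
  summ <- subject_summary(metrics, cfg)

  subjects <- unique(metrics[c("subject_id", "group")])
  subj_rows <- lapply(seq_len(nrow(subjects)), function(i) {
    m <- metrics[metrics$subject_id == subjects$subject_id[i], , drop = FALSE]
    cbind(subjects[i, , drop = FALSE],
          data.frame(antisaccade_performance_pct = antisaccade_performance(m)),
          task_differences(m))
  })
  subj <- do.call(rbind, subj_rows)
  rownames(subj) <- NULL

  ino <- NULL
  if (any(events$group == "HC")) {
    di <- di_cohort(events, cfg)
    hc_per_dir <- tapply(di$group == "HC" & !is.na(di$di), di$direction, sum)
    if (all(hc_per_dir >= 2))  # Z needs a non-degenerate control reference
      ino <- ino_screen(di, cfg)
  }
  structure(list(qc = qc, events = events, metrics = metrics,
                 summary = summ, cohort = cohort_summary(summ),
                 subjects = subj, ino = ino, config = cfg),
            class = "saccade_pipeline")
}

#' @export
print.saccade_pipeline <- function(x, ...) {
  cat("<saccade_pipeline>\n")
  cat(sprintf("  trials after QC      : %d excluded of %d\n",
              sum(x$qc$excluded), nrow(x$qc)))
  cat(sprintf("  primary saccades     : %d (of %d events)\n",
              sum(x$events$primary), nrow(x$events)))
  cat(sprintf("  subjects             : %d\n", nrow(x$subjects)))
  if (!is.null(x$ino))
    cat(sprintf("  subclinical INO      : %d subject-direction(s)\n",
                sum(x$ino$ino, na.rm = TRUE)))
  invisible(x)
}
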