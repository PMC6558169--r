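#' Dysconjugacy index of one subject in one direction
#'
#' Binocular velocity dysconjugacy for large saccades: for every prosaccade
#' trial of the far (largest-eccentricity) condition whose movement is in
#' the given direction and whose primary saccade was accepted in both eyes,
#' the ratio of the abducting eye's to the adducting eye's peak velocity is
#' formed (right eye abducts on rightward saccades, left eye on leftward).
#' The index is the mean of the per-trial ratios (default) or the ratio of
#' the mean velocities (`di_aggregation = "ratio_of_means"`). A healthy,
#' conjugate system gives values near 1; slowed adduction inflates the
#' index.
#'
#' @param events Detected events of one subject ([detect_cohort()] rows,
#'   after practice-trial removal).
#' @param direction Movement direction, `"left"` or `"right"`.
#' @param cfg A [study_config()].
#' @param far_eccentricity Eccentricity of the "long" condition; defaults
#'   to the largest eccentricity present in `events`.
#' @return A list with `di` (`NA` when no binocular far-condition trial
#'   exists in that direction) and `n_trials`.
#' @export
dysconjugacy_index <- function(events, direction, cfg = study_config(),
                               far_eccentricity = NULL) {
  stopifnot(direction %in% c("left", "right"))
  prim <- events[events$primary & events$task == "prosaccade", , drop = FALSE]
  if (is.null(far_eccentricity)) {
    if (nrow(prim) == 0) return(list(di = NA_real_, n_trials = 0L))
    far_eccentricity <- max(prim$eccentricity)
  }
  prim <- prim[prim$eccentricity == far_eccentricity &
                 prim$direction == direction, , drop = FALSE]
  if (nrow(prim) == 0) return(list(di = NA_real_, n_trials = 0L))
  abducting <- direction  # right eye abducts rightward, left eye leftward
  key <- interaction(prim[c("target_direction", "trial_index")], drop = TRUE)
  ratios <- unlist(lapply(split(prim, key), function(d) {
    if (!all(c("left", "right") %in% d$eye)) return(NULL)
    pv_ab <- d$peak_velocity_deg_s[d$eye == abducting]
    pv_ad <- d$peak_velocity_deg_s[d$eye != abducting]
    pv_ab / pv_ad
  }))
  if (is.null(ratios) || length(ratios) == 0)
    return(list(di = NA_real_, n_trials = 0L))
  di <- if (cfg$di_aggregation == "mean_of_ratios") mean(ratios)
        else {
          key2 <- interaction(prim[c("target_direction", "trial_index")],
                              drop = TRUE)
          both <- prim[ave(seq_len(nrow(prim)), key2, FUN = length) == 2, ]
          mean(both$peak_velocity_deg_s[both$eye == abducting]) /
            mean(both$peak_velocity_deg_s[both$eye != abducting])
        }
  list(di = di, n_trials = length(ratios))
}

#' Dysconjugacy index table for a cohort
#'
#' @param events Detected events ([detect_cohort()] output after
#'   [drop_practice()]).
#' @param cfg A [study_config()].
#' @return A data frame with one row per subject x direction: `di` and the
#'   number of binocular trials it is based on.
#' @export
di_cohort <- function(events, cfg = study_config()) {
  subjects <- unique(events[c("subject_id", "group")])
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    ev <- events[events$subject_id == subjects$subject_id[i], , drop = FALSE]
    do.call(rbind, lapply(c("left", "right"), function(d) {
      r <- dysconjugacy_index(ev, d, cfg)
      data.frame(subject_id = subjects$subject_id[i],
                 group = subjects$group[i], direction = d,
                 di = r$di, n_trials = r$n_trials,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-scores of dysconjugacy indices against the control distribution
#'
#' `Z = (DI - mean(DI_HC)) / SD(DI_HC)` with the sample standard deviation
#' of the healthy-control indices of the same direction.
#'
#' @param di Indices to standardise.
#' @param di_hc Healthy-control indices (at least 2, non-degenerate).
#' @return Z-scores.
#' @export
z_scores <- function(di, di_hc) {
  di_hc <- di_hc[!is.na(di_hc)]
  if (length(di_hc) < 2)
    stop("need at least 2 control DI values", call. = FALSE)
  s <- stats::sd(di_hc)
  if (s == 0) stop("control DI distribution is degenerate (SD = 0)",
                   call. = FALSE)
  (di - mean(di_hc)) / s
}

#' Subclinical INO cutoff
#'
#' Threshold on the Z-score: the highest control subject's Z-value plus a
#' margin (default 2). Classification is strict: only Z-values above the
#' cutoff are labelled.
#'
#' @param hc_z Control Z-scores of one direction.
#' @param margin Margin added to the maximum (default 2).
#' @return The cutoff value.
#' @export
ino_cutoff <- function(hc_z, margin = 2) {
  hc_z <- hc_z[!is.na(hc_z)]
  if (length(hc_z) == 0) stop("no control Z-scores available", call. = FALSE)
  max(hc_z) + margin
}

#' Screen a cohort for subclinical INO
#'
#' Per direction: computes every subject's dysconjugacy Z-score against the
#' healthy-control DI distribution of that direction (controls included in
#' their own reference by default; `hc_z_leave_one_out` scores each control
#' against the others), derives the cutoff `max(HC Z) + ino_z_margin`, and
#' labels subjects whose Z exceeds it.
#'
#' @param di_table Output of [di_cohort()].
#' @param cfg A [study_config()].
#' @return `di_table` with `z_di`, `cutoff` and logical `ino` columns.
#' @export
ino_screen <- function(di_table, cfg = study_config()) {
  out <- di_table
  out$z_di <- NA_real_
  out$cutoff <- NA_real_
  out$ino <- NA
  for (d in unique(out$direction)) {
    idx <- which(out$direction == d & !is.na(out$di))
    hc_idx <- idx[out$group[idx] == "HC"]
    di_hc <- out$di[hc_idx]
    out$z_di[idx] <- z_scores(out$di[idx], di_hc)
    if (cfg$hc_z_leave_one_out) {
      for (i in hc_idx)
        out$z_di[i] <- z_scores(out$di[i], out$di[setdiff(hc_idx, i)])
    }
    cut <- ino_cutoff(out$z_di[hc_idx], cfg$ino_z_margin)
    out$cutoff[idx] <- cut
    out$ino[idx] <- out$z_di[idx] > cut
  }
  out
}
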