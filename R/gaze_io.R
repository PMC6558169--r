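#' @keywords internal
"_PACKAGE"

# Long-format gaze table dialect shared by the whole pipeline. One row per
# sample; a trial is identified by (subject_id, task, direction,
# eccentricity, trial_index).
GAZE_COLUMNS <- c("subject_id", "group", "task", "direction", "eccentricity",
                  "trial_index", "t_ms", "x_left", "y_left", "valid_left",
                  "x_right", "y_right", "valid_right")

TRIAL_KEY_COLUMNS <- c("subject_id", "task", "direction", "eccentricity",
                       "trial_index")

#' Read a binocular gaze table
#'
#' Reads the long-format gaze CSV dialect used throughout the pipeline:
#' one row per sample with per-eye horizontal/vertical position (degrees of
#' visual angle, rightward positive, 0 = screen centre) and an integer
#' tracker validity code per eye (0-4; codes above 1 mark unusable samples).
#' Time is milliseconds from stimulus onset within each trial.
#'
#' @param path Path to a CSV file with at least the columns
#'   `subject_id, group, task, direction, eccentricity, trial_index, t_ms,
#'   x_left, y_left, valid_left, x_right, y_right, valid_right`. Extra
#'   columns are preserved untouched.
#' @return A `data.frame` of samples, ordered by trial key and time.
#' @seealso [write_gaze_table()], [split_trials()]
#' @export
read_gaze_table <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(GAZE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("gaze table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_gaze_table(df)
}

#' Write a binocular gaze table
#'
#' Inverse of [read_gaze_table()]: writing a table and reading it back
#' reproduces every field. Rows are grouped by subject and ordered by trial
#' key and time.
#'
#' @param gaze A gaze sample table (see [read_gaze_table()] for columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(gaze, path) {
  if (!is.data.frame(gaze) || nrow(gaze) == 0)
    stop("gaze table must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(GAZE_COLUMNS, names(gaze))
  if (length(missing_cols) > 0)
    stop("gaze table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  gaze <- gaze[order(gaze$subject_id, gaze$task, gaze$direction,
                     gaze$eccentricity, gaze$trial_index, gaze$t_ms), ,
               drop = FALSE]
  utils::write.csv(gaze, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_gaze_table <- function(df) {
  for (col in c("valid_left", "valid_right")) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v != as.integer(v)) || any(v < 0 | v > 4))
      stop("column '", col, "' must hold integer validity codes in [0, 4]",
           call. = FALSE)
  }
  keys <- trial_key(df)
  bad <- tapply(df$t_ms, keys, function(t) is.unsorted(t, strictly = TRUE))
  if (any(bad))
    stop("non-monotone sample times within trial(s): ",
         paste(utils::head(names(bad)[bad], 3), collapse = "; "),
         call. = FALSE)
  df[order(keys, df$t_ms), , drop = FALSE]
}

#' @rdname split_trials
#' @export
trial_key <- function(gaze) {
  interaction(gaze[TRIAL_KEY_COLUMNS], drop = TRUE, lex.order = TRUE, sep = "|")
}

#' Split a gaze table into trials
#'
#' @param gaze A gaze sample table.
#' @return `split_trials()` returns a named list of per-trial data frames
#'   (samples ordered by time); `trial_key()` returns the factor of trial
#'   identifiers used for splitting.
#' @export
split_trials <- function(gaze) {
  split(gaze, trial_key(gaze))
}

#' Signed target position of a trial
#'
#' Leftward targets are negative, rightward positive; magnitude equals the
#' condition eccentricity (9.2 or 18.4 degrees in the default task).
#'
#' @param trial One trial's samples (or any rows sharing direction and
#'   eccentricity).
#' @return Signed target position in degrees.
#' @export
target_position <- function(trial) {
  dir <- unique(trial$direction)
  ecc <- unique(trial$eccentricity)
  stopifnot(length(dir) == 1, length(ecc) == 1)
  ifelse(dir == "left", -1, 1) * ecc
}

#' Convert an on-screen offset to degrees of visual angle
#'
#' @param offset_cm Horizontal offset from the screen centre (cm; signed).
#' @param viewing_distance_cm Eye-to-screen distance (cm; must be positive).
#' @return The visual angle `atan(offset / distance)` in degrees; an odd
#'   function of the offset.
#' @export
#' @examples
#' screen_offset_to_degrees(60 * tan(9.2 * pi / 180), 60)  # 9.2
screen_offset_to_degrees <- function(offset_cm, viewing_distance_cm) {
  if (!is.numeric(viewing_distance_cm) || any(viewing_distance_cm <= 0))
    stop("viewing distance must be positive", call. = FALSE)
  atan2(offset_cm, viewing_distance_cm) * 180 / pi
}

#' @rdname screen_offset_to_degrees
#' @param angle_deg Visual angle in degrees (inverse conversion).
#' @export
degrees_to_screen_offset <- function(angle_deg, viewing_distance_cm) {
  if (!is.numeric(viewing_distance_cm) || any(viewing_distance_cm <= 0))
    stop("viewing distance must be positive", call. = FALSE)
  viewing_distance_cm * tan(angle_deg * pi / 180)
}
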