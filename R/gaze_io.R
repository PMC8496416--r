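# Gaze-recording data model and text I/O.
#
# Positions are stored in degrees of visual angle (rightward positive);
# detection thresholds downstream are angular velocities, so any pixel
# data must be converted at ingestion (see px_to_deg()). Timestamps are
# milliseconds and strictly increasing within a trace.

CANONICAL_COLUMNS <- c("t", "x_left", "y_left", "pupil_left",
                       "x_right", "y_right", "pupil_right")

#' Construct a binocular gaze trace
#'
#' A `gaze_trace` bundles a time-stamped binocular sample table with its
#' nominal sampling rate and free-form provenance metadata. Samples whose
#' pupil signal is zero or missing are flagged as track-lost (blinks);
#' their positions are treated as missing by every downstream velocity
#' computation.
#'
#' @param samples data frame with columns `t` (ms), `x_left`, `y_left`,
#'   `pupil_left`, `x_right`, `y_right`, `pupil_right`. Positions are in
#'   degrees of visual angle.
#' @param rate_hz nominal sampling rate in Hz.
#' @param meta named list of provenance (source file, trial id, ...).
#' @return An object of class `gaze_trace`: a list with elements `samples`
#'   (the validated table, plus logical columns `lost` and `valid`),
#'   `rate_hz` and `meta`.
#' @details Track loss is encoded uniformly: a pupil value of 0, `NA`, or a
#'   `.` token in a source file all set `lost = TRUE`. The `valid` column
#'   starts as `!lost` and is further cleared by [mask_blinks()].
#' @examples
#' s <- data.frame(t = 0:4, x_left = 0, y_left = 0, pupil_left = 1000,
#'                 x_right = 0, y_right = 0, pupil_right = 1000)
#' gaze_trace(s, rate_hz = 1000)
#' @export
gaze_trace <- function(samples, rate_hz, meta = list()) {
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(samples))
  if (length(missing_cols) > 0L) {
    stop_okncs(sprintf("gaze samples lack column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "okncs_format_error")
  }
  samples <- as.data.frame(samples)[CANONICAL_COLUMNS]
  t <- samples$t
  if (anyNA(t)) {
    stop_okncs("sample timestamps contain missing values", "okncs_data_error")
  }
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L) {
    stop_okncs(sprintf(
      "timestamps must be strictly increasing; violation at row %d",
      bad[1L] + 1L), "okncs_data_error", row = bad[1L] + 1L)
  }
  lost <- is_lost(samples$pupil_left) | is_lost(samples$pupil_right) |
    !is.finite(samples$x_left) | !is.finite(samples$x_right)
  samples$lost <- lost
  samples$valid <- !lost
  structure(list(samples = samples, rate_hz = rate_hz, meta = meta),
            class = "gaze_trace")
}

is_lost <- function(pupil) {
  is.na(pupil) | pupil <= 0
}

#' @export
print.gaze_trace <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- if (n > 1L) (x$samples$t[n] - x$samples$t[1L]) / 1000 else 0
  cat(sprintf("<gaze_trace> %d samples @ %g Hz (%.2f s), %d track-lost\n",
              n, x$rate_hz, dur, sum(x$samples$lost)))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L, x$meta)
  if (length(scalars) > 0L) {
    cat("  meta:", paste(names(scalars), unlist(lapply(scalars, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a gaze trace
#' @param x a `gaze_trace`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' Convert pixel coordinates to degrees of visual angle
#'
#' @param px pixel offset from the screen centre.
#' @param geometry a [screen_geometry()].
#' @return angle in degrees.
#' @export
px_to_deg <- function(px, geometry) {
  mm <- px * geometry$pixel_pitch_mm
  atan2(mm, geometry$viewing_distance_cm * 10) * 180 / pi
}

#' Read a delimited gaze-sample file
#'
#' Expects a header row naming the seven canonical sample fields (see
#' [gaze_trace()]); `dialect` maps non-standard header names onto them.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical names to the
#'   file's column names, e.g. `c(t = "time_ms")`. Unmapped fields use
#'   their canonical names.
#' @param rate_hz sampling rate; if `NULL`, inferred from the median
#'   timestamp spacing.
#' @return a [gaze_trace()].
#' @export
read_gaze_csv <- function(path, dialect = NULL, rate_hz = NULL) {
  if (!file.exists(path)) {
    stop_okncs(sprintf("no such file: %s", path), "okncs_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  missing_cols <- cols[!(cols %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop_okncs(sprintf("file %s lacks column(s): %s", path,
                       paste(missing_cols, collapse = ", ")),
               "okncs_format_error")
  }
  samples <- stats::setNames(raw[unname(cols)], names(cols))
  if (is.null(rate_hz)) {
    dt <- stats::median(diff(samples$t))
    rate_hz <- if (is.finite(dt) && dt > 0) 1000 / dt else NA_real_
  }
  gaze_trace(samples, rate_hz = rate_hz, meta = list(source = path))
}

#' Write a gaze trace as delimited text
#'
#' Emits the canonical header `t,x_left,y_left,pupil_left,x_right,y_right,
#' pupil_right` with positions rounded to a fixed decimal precision, so
#' that `read_gaze_csv(write_gaze_csv(x))` is the identity at that
#' precision.
#'
#' @param trace a [gaze_trace()].
#' @param path output path.
#' @param digits decimal places for positions and timestamps.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(trace, path, digits = 4L) {
  s <- trace$samples[CANONICAL_COLUMNS]
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], function(col) round(col, digits))
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE, na = "NaN")
  invisible(path)
}

#' Read a minimal EyeLink-ASC-style sample file
#'
#' Lines whose first whitespace-separated token parses as a number are
#' sample lines with fields `t xL yL pL xR yR pR`; all other lines
#' (messages, events) are ignored. A `.` or empty field marks missing
#' data and yields a track-lost sample.
#'
#' @param path file path.
#' @param rate_hz sampling rate; inferred from timestamps if `NULL`.
#' @return a [gaze_trace()].
#' @export
read_asc_samples <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) {
    stop_okncs(sprintf("no such file: %s", path), "okncs_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  first <- vapply(toks, function(x) if (length(x) >= 1L) x[[1L]] else "",
                  character(1))
  is_sample <- suppressWarnings(!is.na(as.numeric(first)))
  toks <- toks[is_sample]
  if (length(toks) == 0L) {
    stop_okncs(sprintf("no sample lines in %s", path), "okncs_empty_error")
  }
  num <- function(i) {
    vapply(toks, function(x) {
      v <- if (length(x) >= i) x[[i]] else "."
      if (v == "." || v == "") NA_real_
      else suppressWarnings(as.numeric(v))
    }, numeric(1))
  }
  samples <- data.frame(t = num(1L),
                        x_left = num(2L), y_left = num(3L), pupil_left = num(4L),
                        x_right = num(5L), y_right = num(6L), pupil_right = num(7L))
  if (is.null(rate_hz)) {
    dt <- stats::median(diff(samples$t))
    rate_hz <- if (is.finite(dt) && dt > 0) 1000 / dt else NA_real_
  }
  gaze_trace(samples, rate_hz = rate_hz, meta = list(source = path))
}

#' Write a gaze trace in the minimal ASC sample dialect
#'
#' @param trace a [gaze_trace()].
#' @param path output path.
#' @param digits decimal places.
#' @return `path`, invisibly.
#' @export
write_asc_samples <- function(trace, path, digits = 4L) {
  s <- trace$samples
  fmt <- function(v) ifelse(is.na(v), ".", formatC(round(v, digits),
                                                   format = "fg", digits = 15))
  lines <- paste(fmt(s$t), fmt(s$x_left), fmt(s$y_left), fmt(s$pupil_left),
                 fmt(s$x_right), fmt(s$y_right), fmt(s$pupil_right),
                 sep = "\t")
  writeLines(c("** okncs ASC sample export", lines), path)
  invisible(path)
}

#' Trial record
#'
#' Captures one stimulus presentation: the stimulus, the detector's
#' decision, when the trial ended, and the detected events.
#'
#' @param trial_id identifier.
#' @param stimulus a [stimulus_spec()].
#' @param outcome `"seen"` or `"not_seen"`.
#' @param abort_time_ms time of the robust-OKN decision or timeout.
#' @param events data frame of detected quick-/slow-phase events.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(trial_id, stimulus, outcome, abort_time_ms,
                         events = NULL) {
  outcome <- match.arg(outcome, c("seen", "not_seen"))
  if (!is.null(stimulus$duration_max_s) &&
      abort_time_ms > stimulus$duration_max_s * 1000 + 1e-6) {
    stop_okncs("abort_time_ms exceeds the trial timeout", "okncs_data_error")
  }
  structure(list(trial_id = trial_id, stimulus = stimulus, outcome = outcome,
                 abort_time_ms = abort_time_ms, events = events),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s: %s at %.0f ms (contrast %.4g)\n",
              x$trial_id, x$outcome, x$abort_time_ms,
              x$stimulus$contrast %||% NA))
  invisible(x)
}
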