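# Post-hoc (offline) OKN analysis at the recording's full sampling rate:
# blink masking, quick-phase detection, slow-phase validation and the
# robust-OKN decision.

#' Validate a candidate slow phase between two quick phases
#'
#' Takes the inter-saccadic interval `(t_from, t_to)`, shrinks it by
#' `trim_ms` at both ends (saccadic-overshoot protection), smooths the
#' horizontal position with a centered moving average, estimates the mean
#' velocity per eye, averages across valid eyes and accepts the segment
#' as a slow phase iff the velocity sign matches the stimulus drift
#' direction and its magnitude reaches the slow-phase threshold.
#'
#' @param trace a [gaze_trace()] (blink-masked or not).
#' @param t_from,t_to interval bounds in ms: end of the opening saccade
#'   and start of the closing saccade.
#' @param direction stimulus drift direction, `+1` or `-1`.
#' @param config a [detector_config()].
#' @return A one-row data frame (`t_start`, `t_end`, `mean_velocity`,
#'   `direction_match`) for a valid slow phase, or `NULL` if the segment
#'   is too short, flat, below threshold, or drifts against the stimulus.
#' @export
validate_slow_phase <- function(trace, t_from, t_to, direction, config) {
  trim <- config$trim_ms
  lo <- t_from + trim
  hi <- t_to - trim
  if (hi <= lo) return(NULL)
  s <- trace$samples
  idx <- which(s$t >= lo & s$t <= hi)
  if (length(idx) < max(2L, config$smooth_window_samples)) return(NULL)
  t_ms <- s$t[idx]
  mean_v_eye <- function(x) {
    x[!s$valid[idx]] <- NA_real_
    xs <- moving_average(x, config$smooth_window_samples)
    fin <- which(is.finite(xs))
    if (length(fin) < 2L) return(NA_real_)
    if (config$sp_velocity_estimator == "endpoint") {
      i0 <- fin[1L]; i1 <- fin[length(fin)]
      if (t_ms[i1] <= t_ms[i0]) return(NA_real_)
      (xs[i1] - xs[i0]) / (t_ms[i1] - t_ms[i0]) * 1000
    } else {
      dv <- diff(xs) / diff(t_ms) * 1000
      dv <- dv[is.finite(dv)]
      if (length(dv) == 0L) return(NA_real_)
      mean(dv)
    }
  }
  v_eyes <- c(mean_v_eye(s$x_left[idx]), mean_v_eye(s$x_right[idx]))
  v_eyes <- v_eyes[is.finite(v_eyes)]
  if (length(v_eyes) == 0L) return(NULL)
  v <- mean(v_eyes)
  match_dir <- sign(v) == sign(direction)
  if (!match_dir || abs(v) < config$sp_velocity_threshold_dps) return(NULL)
  data.frame(t_start = lo, t_end = hi, mean_velocity = v,
             direction_match = TRUE)
}

#' Offline OKN analysis of one recorded trial
#'
#' Reference pipeline at the full sampling rate: blink masking with a
#' protective buffer, five-point velocity transform, median-based noise
#' threshold over the configured noise window, binocular quick-phase
#' detection with 50 ms overshoot merging, slow-phase validation of every
#' inter-saccadic gap, and the robust-OKN decision (at least
#' `robust_count` validated slow phases).
#'
#' @param trace a [gaze_trace()] covering the stimulus presentation.
#' @param stimulus a [stimulus_spec()].
#' @param config a [detector_config()] (use `mode = "offline"`).
#' @return An object of class `okn_detection`: list with `okn_present`,
#'   `n_valid_slow_phases`, `quick_phases`, `slow_phases`,
#'   `decision_time_ms` (start of the saccade closing the decisive slow
#'   phase; end of trace when no decision), `noise` and `mode`.
#' @export
analyze_trial_offline <- function(trace, stimulus,
                                  config = detector_config("offline")) {
  if (config$sp_velocity_threshold_dps > 2 * stimulus$velocity_dps) {
    warning("slow-phase velocity threshold exceeds twice the stimulus speed")
  }
  trace <- mask_blinks(trace, config$blink_buffer_ms)
  v <- compute_velocity(trace)
  t0 <- trace$samples$t[1L]
  win <- which(trace$samples$t - t0 < noise_window_ms(config))
  noise <- noise_threshold(v, window = win, lambda_noise = config$lambda_noise)
  qp <- detect_saccades(v, noise,
                        min_duration_ms = config$min_saccade_duration_ms,
                        min_separation_ms = config$min_saccade_separation_ms,
                        binocular_required = config$binocular_required)
  sp <- NULL
  decision_time <- NA_real_
  if (nrow(qp) >= 2L) {
    for (i in seq_len(nrow(qp) - 1L)) {
      ev <- validate_slow_phase(trace, qp$t_end[i], qp$t_start[i + 1L],
                                stimulus$direction, config)
      if (!is.null(ev)) {
        ev$closing_saccade_t <- qp$t_start[i + 1L]
        sp <- rbind(sp, ev)
        if (nrow(sp) == config$robust_count && is.na(decision_time)) {
          decision_time <- qp$t_start[i + 1L]
        }
      }
    }
  }
  n_sp <- if (is.null(sp)) 0L else nrow(sp)
  present <- n_sp >= config$robust_count
  if (!present) decision_time <- trace$samples$t[nrow(trace$samples)]
  structure(list(okn_present = present, n_valid_slow_phases = n_sp,
                 quick_phases = qp, slow_phases = sp,
                 decision_time_ms = decision_time, noise = noise,
                 mode = "offline", stimulus = stimulus, config = config),
            class = "okn_detection")
}

#' @export
print.okn_detection <- function(x, ...) {
  cat(sprintf(
    "<okn_detection> [%s] %s: %d quick phase(s), %d valid slow phase(s), decision at %.0f ms\n",
    x$mode, if (x$okn_present) "OKN present (seen)" else "no OKN (not seen)",
    nrow(x$quick_phases), x$n_valid_slow_phases, x$decision_time_ms))
  invisible(x)
}
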