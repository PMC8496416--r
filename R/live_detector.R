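# Causal frame-by-frame OKN detection coupled to the display refresh rate.
#
# The live analysis decimates gaze to one representative sample per display
# frame, spends the first noise_window_frames exclusively on noise
# estimation, then scans velocities for quick phases starting from the last
# detected saccade. Whenever a new quick phase is confirmed, the preceding
# inter-saccadic segment is validated as a slow phase; as soon as
# robust_count slow phases are valid the trial is decided "seen". There is
# deliberately no blink masking in live mode: a non-finite frame is treated
# as track loss and simply breaks supra-threshold runs.

#' Decimate a gaze trace to display frames
#'
#' One representative sample per frame: the latest eye-tracker sample at
#' or before each frame boundary (boundaries at the first timestamp plus
#' integer multiples of the frame period).
#'
#' @param trace a [gaze_trace()].
#' @param frame_rate_hz display refresh rate.
#' @return data frame with the canonical sample columns plus `frame` and
#'   `valid`; zero rows for an empty trace.
#' @export
downsample_to_frames <- function(trace, frame_rate_hz = 120) {
  s <- trace$samples
  if (nrow(s) == 0L) return(cbind(s, frame = integer(0)))
  period <- 1000 / frame_rate_hz
  t0 <- s$t[1L]
  n_frames <- floor((s$t[nrow(s)] - t0) / period) + 1L
  boundaries <- t0 + (seq_len(n_frames) - 1L) * period
  idx <- findInterval(boundaries + 1e-9, s$t)
  out <- s[idx, , drop = FALSE]
  out$frame <- seq_len(n_frames)
  out$t_frame <- boundaries
  rownames(out) <- NULL
  out
}

# Core causal scan of a complete frame series. Called both by the batch
# replay (run_live) and, on the growing prefix, by the streaming API; the
# decision at frame k depends only on frames <= k by construction (an
# event's qualification frame accounts for the two-frame kernel lookahead).
live_scan <- function(frames, stimulus, config) {
  K <- nrow(frames)
  W <- config$noise_window_frames
  timeout_ms <- config$timeout_s * 1000
  t_rel <- frames$t_frame - frames$t_frame[1L]
  # the presentation spans [0, timeout); the frame starting the last frame
  # period already closes the trial, so "not seen" is stamped at the
  # timeout itself
  period <- 1000 / config$frame_rate_hz
  timeout_frame <- {
    hit <- which(t_rel >= timeout_ms - period - 1e-9)
    if (length(hit)) hit[1L] else Inf
  }
  min_dur_frames <- max(1L, ceiling(config$min_saccade_duration_ms *
                                      config$frame_rate_hz / 1000 - 1e-9))
  out <- list(phase = if (K < W) "noise_estimation" else "scanning",
              frames_seen = K, noise = NULL, quick_phases = NULL,
              slow_phases = NULL, valid_slow_phases = 0L,
              last_saccade_end = NA_real_, open_saccade = NULL,
              decided = FALSE, decision = NA_character_,
              decision_time_ms = NA_real_, decision_frame = NA_integer_)
  undecided_timeout <- function(out) {
    if (is.finite(timeout_frame) && K >= timeout_frame) {
      out$decided <- TRUE
      out$decision <- "not_seen"
      out$decision_time_ms <- frames$t_frame[1L] + timeout_ms
      out$decision_frame <- as.integer(timeout_frame)
      out$phase <- "decided"
    }
    out
  }
  if (K < max(W, 5L)) return(undecided_timeout(out))

  dt <- 1 / config$frame_rate_hz
  x_l <- ifelse(frames$valid, frames$x_left, NA_real_)
  x_r <- ifelse(frames$valid, frames$x_right, NA_real_)
  vel <- function(x) {
    v <- rep(NA_real_, K)
    idx <- 3:(K - 2L)
    v[idx] <- (x[idx + 2L] + x[idx + 1L] - x[idx - 1L] - x[idx - 2L]) / (6 * dt)
    v
  }
  v_l <- vel(x_l)
  v_r <- vel(x_r)

  # noise threshold: pure function of the first W frames
  noise_idx <- 3:(W - 2L)
  noise <- tryCatch(
    noise_threshold(data.frame(t = frames$t_frame, v_left = v_l,
                               v_right = v_r),
                    window = noise_idx, lambda_noise = config$lambda_noise),
    okncs_noise_error = function(e) NULL)
  out$noise <- noise
  if (is.null(noise)) return(undecided_timeout(out))

  J <- K - 2L           # last frame with a computable velocity
  supra_l <- is.finite(v_l) & abs(v_l) > noise$eta_left
  supra_r <- is.finite(v_r) & abs(v_r) > noise$eta_right
  supra_l[seq_len(W)] <- FALSE   # noise period is never scanned
  supra_r[seq_len(W)] <- FALSE

  frame_trace <- list(samples = data.frame(
    t = frames$t_frame, x_left = frames$x_left, x_right = frames$x_right,
    valid = frames$valid))

  window_start <- W + 1L
  prev_end_t <- NA_real_
  have_prev <- FALSE
  qp_rows <- list()
  sp_rows <- list()
  n_sp <- 0L
  repeat {
    if (window_start > J) break
    win <- window_start:J
    ev <- binocular_run_union(supra_l[win], supra_r[win],
                              config$binocular_required)
    if (nrow(ev) > 0L) {
      ev[, 1L] <- ev[, 1L] + window_start - 1L
      ev[, 2L] <- ev[, 2L] + window_start - 1L
      ev <- ev[(ev[, 2L] - ev[, 1L] + 1L) >= min_dur_frames, , drop = FALSE]
    }
    if (nrow(ev) == 0L) break
    # qualification frame of each event: run length reaches the minimum
    # duration and (if required) a both-eyes sample has arrived, plus the
    # two-frame kernel lookahead
    qual <- vapply(seq_len(nrow(ev)), function(i) {
      s0 <- ev[i, 1L]
      b <- if (config$binocular_required) {
        both <- which(supra_l[s0:ev[i, 2L]] & supra_r[s0:ev[i, 2L]])
        s0 + both[1L] - 1L
      } else s0
      max(s0 + min_dur_frames - 1L, b) + 2L
    }, numeric(1))
    act <- order(qual, ev[, 1L])[1L]
    s0 <- ev[act, 1L]
    e0 <- ev[act, 2L]
    q_frame <- qual[act]
    if (q_frame > K) break                      # not yet confirmed
    # decision for "seen" can only fall before the timeout
    if (q_frame >= timeout_frame) break
    qp_rows[[length(qp_rows) + 1L]] <-
      data.frame(t_start = frames$t_frame[s0], t_end = frames$t_frame[e0],
                 start_idx = s0, end_idx = e0)
    if (have_prev) {
      spev <- validate_slow_phase(frame_trace, prev_end_t,
                                  frames$t_frame[s0], stimulus$direction,
                                  config)
      if (!is.null(spev)) {
        spev$closing_saccade_t <- frames$t_frame[s0]
        sp_rows[[length(sp_rows) + 1L]] <- spev
        n_sp <- n_sp + 1L
        if (n_sp >= config$robust_count) {
          out$decided <- TRUE
          out$decision <- "seen"
          out$decision_frame <- as.integer(q_frame)
          out$decision_time_ms <- frames$t_frame[q_frame]
          break
        }
      }
    }
    # wait for the event to close before scanning further
    if (e0 >= J) {
      out$open_saccade <- c(start = s0, end = NA)
      break
    }
    have_prev <- TRUE
    prev_end_t <- frames$t_frame[e0]
    window_start <- e0 + 1L
  }
  out$last_saccade_end <- if (have_prev) prev_end_t else NA_real_
  out$valid_slow_phases <- n_sp
  out$quick_phases <- if (length(qp_rows)) do.call(rbind, qp_rows) else NULL
  out$slow_phases <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
  if (!out$decided) out <- undecided_timeout(out)
  out
}

#' Initialize a live OKN detection state
#'
#' @param stimulus a [stimulus_spec()].
#' @param config a [detector_config()] with `mode = "live"`.
#' @return an object of class `live_state` (a mutable environment) to be
#'   advanced with [feed_frame()].
#' @export
live_state <- function(stimulus, config = detector_config("live")) {
  e <- new.env(parent = emptyenv())
  cap <- as.integer(ceiling(config$timeout_s * config$frame_rate_hz)) + 64L
  e$t <- e$x_left <- e$x_right <- rep(NA_real_, cap)
  e$valid <- rep(NA, cap)
  e$k <- 0L
  e$stimulus <- stimulus
  e$config <- config
  e$scan <- NULL
  e$decided <- FALSE
  e$decision <- NA_character_
  e$decision_time_ms <- NA_real_
  class(e) <- "live_state"
  e
}

#' Feed one display frame to the live detector
#'
#' Advances the streaming OKN detection by one frame. Frames must arrive
#' in order at the nominal frame rate; one representative gaze sample per
#' frame. During the first `noise_window_frames` frames the sample only
#' accumulates into the noise estimate; afterwards quick phases are
#' detected incrementally and each newly confirmed quick phase triggers
#' validation of the preceding inter-saccadic segment. The decision
#' (`"seen"` as soon as `robust_count` slow phases are valid, `"not_seen"`
#' at the timeout) is returned and stored in the state.
#'
#' @param state a [live_state()].
#' @param frame_samples list or one-row data frame with elements `t` (ms),
#'   `x_left`, `x_right` (deg); non-finite positions are treated as track
#'   loss.
#' @return the updated state, invisibly; inspect `state$decided`,
#'   `state$decision`, `state$decision_time_ms`.
#' @export
feed_frame <- function(state, frame_samples) {
  if (state$decided) {
    warning("frame received after the trial was decided; ignored")
    return(invisible(state))
  }
  k <- state$k + 1L
  if (k > length(state$t)) {  # grow (only when fed past the timeout)
    grow <- function(v) c(v, rep(NA_real_, 64L))
    state$t <- grow(state$t); state$x_left <- grow(state$x_left)
    state$x_right <- grow(state$x_right); state$valid <- c(state$valid, rep(NA, 64L))
  }
  xl <- as.numeric(frame_samples$x_left)
  xr <- as.numeric(frame_samples$x_right)
  lost <- !is.finite(xl) || !is.finite(xr) ||
    isTRUE(!(frame_samples$valid %||% TRUE))
  state$t[k] <- as.numeric(frame_samples$t)
  state$x_left[k] <- xl
  state$x_right[k] <- xr
  state$valid[k] <- !lost
  state$k <- k
  idx <- seq_len(k)
  frames <- data.frame(t_frame = state$t[idx], x_left = state$x_left[idx],
                       x_right = state$x_right[idx], valid = state$valid[idx])
  res <- live_scan(frames, state$stimulus, state$config)
  state$scan <- res
  if (res$decided) {
    state$decided <- TRUE
    state$decision <- res$decision
    state$decision_time_ms <- res$decision_time_ms
  }
  invisible(state)
}

#' @export
print.live_state <- function(x, ...) {
  cat(sprintf("<live_state> %d frames; %s\n", x$k,
              if (x$decided) sprintf("decided: %s at %.0f ms", x$decision,
                                     x$decision_time_ms)
              else sprintf("undecided (%d valid slow phases)",
                           x$scan$valid_slow_phases %||% 0L)))
  invisible(x)
}

#' Live OKN analysis of a recorded trial (batch replay)
#'
#' Replays a full-rate recording through the causal live detector:
#' decimates to display frames and runs the same scan that [feed_frame()]
#' performs incrementally, in one vectorized pass. Decisions and decision
#' times are identical to streaming the frames one by one.
#'
#' @param trace a [gaze_trace()].
#' @param stimulus a [stimulus_spec()].
#' @param config a [detector_config()] with `mode = "live"`.
#' @return an `okn_detection` object (see [analyze_trial_offline()]) with
#'   `mode = "live"`.
#' @export
run_live <- function(trace, stimulus, config = detector_config("live")) {
  if (isTRUE(config$live_full_rate)) {
    # analyse every sample; the noise window keeps its 283 ms duration
    frames <- trace$samples
    frames$t_frame <- frames$t
    config$noise_window_frames <-
      as.integer(round(noise_window_ms(config) * trace$rate_hz / 1000))
    config$frame_rate_hz <- trace$rate_hz
  } else {
    frames <- downsample_to_frames(trace, config$frame_rate_hz)
  }
  res <- live_scan(frames, stimulus, config)
  if (!res$decided) {
    # trace ended before the timeout: no robust OKN seen
    res$decision <- "not_seen"
    res$decision_time_ms <- frames$t_frame[nrow(frames)]
  }
  qp <- res$quick_phases
  if (is.null(qp)) qp <- data.frame(t_start = numeric(0), t_end = numeric(0),
                                    start_idx = integer(0), end_idx = integer(0))
  structure(list(okn_present = identical(res$decision, "seen"),
                 n_valid_slow_phases = res$valid_slow_phases,
                 quick_phases = qp, slow_phases = res$slow_phases,
                 decision_time_ms = res$decision_time_ms, noise = res$noise,
                 mode = "live", stimulus = stimulus, config = config),
            class = "okn_detection")
}

#' Run the live and offline detectors on the same recording
#'
#' The software analogue of a live-vs-offline concordance evaluation:
#' the live detector sees the frame-decimated series, the offline
#' detector the full-rate series.
#'
#' @param trace a full-rate [gaze_trace()].
#' @param stimulus a [stimulus_spec()].
#' @param config_live,config_offline detector configurations.
#' @return list with elements `live` and `offline` (both `okn_detection`)
#'   plus `concordant` (logical).
#' @export
replay_compare <- function(trace, stimulus,
                           config_live = detector_config("live"),
                           config_offline = detector_config("offline")) {
  live <- run_live(trace, stimulus, config_live)
  offline <- analyze_trial_offline(trace, stimulus, config_offline)
  list(live = live, offline = offline,
       concordant = live$okn_present == offline$okn_present)
}
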