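# Velocity transform, median-based noise threshold and velocity-threshold
# event detection shared by the offline and live OKN detectors.

#' Horizontal gaze velocity by five-point central difference
#'
#' Computes per-eye horizontal velocity with the five-point kernel
#' `v[n] = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 * dt)`, the transform
#' used by velocity-threshold (micro)saccade detection. The kernel is
#' exact for affine position signals and attenuates sample noise.
#'
#' @param trace a [gaze_trace()].
#' @param axis only `"horizontal"` is supported; OKN analysis here is
#'   restricted to the horizontal plane.
#' @return A `velocity_trace`: data frame with columns `t` (ms), `v_left`,
#'   `v_right` (deg/s). The first and last two samples are `NA` (kernel
#'   margin), as is any sample whose kernel window touches an invalid
#'   (track-lost or blink-masked) sample.
#' @export
compute_velocity <- function(trace, axis = "horizontal") {
  axis <- match.arg(axis, "horizontal")
  s <- trace$samples
  n <- nrow(s)
  if (n < 5L) {
    stop_okncs("velocity needs at least 5 samples", "okncs_insufficient_data")
  }
  dt <- 1 / trace$rate_hz
  one_eye <- function(x) {
    x[!s$valid] <- NA_real_
    v <- rep(NA_real_, n)
    idx <- 3:(n - 2L)
    v[idx] <- (x[idx + 2L] + x[idx + 1L] - x[idx - 1L] - x[idx - 2L]) / (6 * dt)
    v
  }
  out <- data.frame(t = s$t, v_left = one_eye(s$x_left),
                    v_right = one_eye(s$x_right))
  class(out) <- c("velocity_trace", "data.frame")
  attr(out, "rate_hz") <- trace$rate_hz
  out
}

#' Median-based velocity noise threshold
#'
#' Estimates each eye's velocity noise level with the median estimator
#' `sigma^2 = median(v^2) - median(v)^2`, which is robust to the rare
#' high-velocity samples of quick phases, and sets the detection
#' threshold `eta = lambda_noise * sigma` per eye.
#'
#' @param v a `velocity_trace` from [compute_velocity()].
#' @param window integer vector of sample indices to estimate over
#'   (default: all samples).
#' @param lambda_noise dimensionless threshold multiplier (default 7).
#' @return A `noise_threshold`: list with `sigma_left`, `sigma_right`,
#'   `eta_left`, `eta_right` (deg/s) and `lambda_noise`.
#' @export
noise_threshold <- function(v, window = seq_len(nrow(v)), lambda_noise = 7) {
  est <- function(vec) {
    vec <- vec[window]
    vec <- vec[is.finite(vec)]
    if (length(vec) < 5L) {
      stop_okncs("noise window holds fewer than 5 valid velocities",
                 "okncs_noise_error")
    }
    # numerical guard: the estimator can go epsilon-negative on ties
    sqrt(max(0, stats::median(vec^2) - stats::median(vec)^2))
  }
  sl <- est(v$v_left)
  sr <- est(v$v_right)
  structure(list(sigma_left = sl, sigma_right = sr,
                 lambda_noise = lambda_noise,
                 eta_left = lambda_noise * sl, eta_right = lambda_noise * sr),
            class = "noise_threshold")
}

#' @export
print.noise_threshold <- function(x, ...) {
  cat(sprintf(
    "<noise_threshold> sigma L/R = %.3f/%.3f deg/s, lambda = %g, eta L/R = %.2f/%.2f deg/s\n",
    x$sigma_left, x$sigma_right, x$lambda_noise, x$eta_left, x$eta_right))
  invisible(x)
}

# Binocular event intervals from per-eye supra-threshold logical vectors.
# A monocular run is kept only if it overlaps a run of the other eye by at
# least one sample; overlapping runs are merged transitively (connected
# components over the interval-overlap relation) and the union interval is
# reported. With binocular_required = FALSE every monocular run is an event.
binocular_run_union <- function(supra_left, supra_right, binocular_required) {
  rl <- logical_runs(supra_left)
  rr <- logical_runs(supra_right)
  if (!binocular_required) {
    runs <- rbind(rl, rr)
    if (nrow(runs) == 0L) return(runs)
    runs <- runs[order(runs[, 1L]), , drop = FALSE]
    # merge any overlapping/touching runs from the two eyes
    merged <- runs[1L, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1L]) {
      k <- nrow(merged)
      if (runs[i, 1L] <= merged[k, 2L] + 0L) {
        merged[k, 2L] <- max(merged[k, 2L], runs[i, 2L])
      } else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
    return(merged)
  }
  if (nrow(rl) == 0L || nrow(rr) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  events <- NULL
  used_r <- rep(FALSE, nrow(rr))
  for (i in seq_len(nrow(rl))) {
    ov <- which(rr[, 1L] <= rl[i, 2L] & rr[, 2L] >= rl[i, 1L])
    if (length(ov) == 0L) next
    used_r[ov] <- TRUE
    events <- rbind(events, c(min(rl[i, 1L], rr[ov, 1L]),
                              max(rl[i, 2L], rr[ov, 2L])))
  }
  if (is.null(events)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  # transitive closure: merge event intervals that overlap (chained overlap
  # through shared right-eye runs)
  events <- events[order(events[, 1L]), , drop = FALSE]
  merged <- events[1L, , drop = FALSE]
  for (i in seq_len(nrow(events))[-1L]) {
    k <- nrow(merged)
    if (events[i, 1L] <= merged[k, 2L]) {
      merged[k, 2L] <- max(merged[k, 2L], events[i, 2L])
    } else merged <- rbind(merged, events[i, , drop = FALSE])
  }
  colnames(merged) <- c("start", "end")
  merged
}

#' Detect saccades (OKN quick phases) by velocity thresholding
#'
#' Finds maximal runs of supra-threshold horizontal velocity
#' (`|v| > eta`, per eye), applies the binocular-overlap criterion, drops
#' runs shorter than `min_duration_ms`, and merges events separated by
#' less than `min_separation_ms` (overshoot protection).
#'
#' @param v a `velocity_trace`.
#' @param eta a [noise_threshold()].
#' @param min_duration_ms minimum event duration (sample count times the
#'   sampling period).
#' @param min_separation_ms events closer than this are merged into one.
#' @param binocular_required if `TRUE` (default) a monocular run is kept
#'   only if it overlaps a run in the other eye by at least one sample;
#'   the merged interval is reported.
#' @return data frame of class `saccade_events` with columns `t_start`,
#'   `t_end` (ms), `start_idx`, `end_idx`, `peak_velocity` (signed deg/s,
#'   largest magnitude across eyes), `direction` (+1/-1) and `binocular`.
#'   Zero rows when nothing is detected. Intervals are disjoint and sorted.
#' @export
detect_saccades <- function(v, eta, min_duration_ms = 6,
                            min_separation_ms = 50,
                            binocular_required = TRUE) {
  stopifnot(min_separation_ms >= 0)
  dt_ms <- 1000 / attr(v, "rate_hz")
  supra_l <- is.finite(v$v_left) & abs(v$v_left) > eta$eta_left
  supra_r <- is.finite(v$v_right) & abs(v$v_right) > eta$eta_right
  runs <- binocular_run_union(supra_l, supra_r, binocular_required)
  if (nrow(runs) > 0L) {
    dur <- (runs[, 2L] - runs[, 1L] + 1L) * dt_ms
    runs <- runs[dur >= min_duration_ms, , drop = FALSE]
  }
  # merge events with inter-event gap below min_separation_ms
  if (nrow(runs) > 1L && min_separation_ms > 0) {
    merged <- runs[1L, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1L]) {
      k <- nrow(merged)
      gap_ms <- (runs[i, 1L] - merged[k, 2L] - 1L) * dt_ms
      if (gap_ms < min_separation_ms) {
        merged[k, 2L] <- runs[i, 2L]
      } else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
    runs <- merged
  }
  events <- saccade_events_from_runs(runs, v, supra_l, supra_r)
  events
}

saccade_events_from_runs <- function(runs, v, supra_l, supra_r) {
  n <- nrow(runs)
  peak <- direction <- numeric(n)
  binoc <- logical(n)
  for (i in seq_len(n)) {
    idx <- runs[i, 1L]:runs[i, 2L]
    vv <- c(v$v_left[idx], v$v_right[idx])
    vv <- vv[is.finite(vv)]
    peak[i] <- vv[which.max(abs(vv))]
    m <- mean(vv)
    direction[i] <- if (m >= 0) 1 else -1
    binoc[i] <- any(supra_l[idx] & supra_r[idx])
  }
  out <- data.frame(
    t_start = if (n) v$t[runs[, 1L]] else numeric(0),
    t_end = if (n) v$t[runs[, 2L]] else numeric(0),
    start_idx = if (n) runs[, 1L] else integer(0),
    end_idx = if (n) runs[, 2L] else integer(0),
    peak_velocity = peak, direction = direction, binocular = binoc)
  class(out) <- c("saccade_events", "data.frame")
  out
}

#' Mask blink intervals with a protective buffer
#'
#' Every maximal run of track-lost samples, extended by `buffer_ms` on
#' each side, is flagged invalid so that downstream velocities over those
#' samples are `NA` (blink-related artefact protection).
#'
#' @param trace a [gaze_trace()].
#' @param buffer_ms buffer on each side of a track-loss run (default 50).
#' @return The trace with its `valid` column cleared over the dilated
#'   blink intervals.
#' @export
mask_blinks <- function(trace, buffer_ms = 50) {
  stopifnot(buffer_ms >= 0)
  s <- trace$samples
  runs <- logical_runs(s$lost)
  if (nrow(runs) == 0L) return(trace)
  invalid <- !s$valid
  for (i in seq_len(nrow(runs))) {
    t0 <- s$t[runs[i, 1L]] - buffer_ms
    t1 <- s$t[runs[i, 2L]] + buffer_ms
    invalid <- invalid | (s$t >= t0 & s$t <= t1)
  }
  trace$samples$valid <- !invalid
  trace
}
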