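# Shared detector configuration for the offline and live OKN analyses.

#' OKN detector configuration
#'
#' All tunables of the quick-phase/slow-phase detection pipeline. The
#' defaults reproduce the reference setup: noise estimated over the first
#' 34 display frames (283 ms at 120 Hz), threshold multiplier
#' `lambda_noise = 7`, 5-sample moving-average smoothing, ~17 ms (two
#' screen refreshes) saccadic-overshoot trimming, 50 ms blink buffer and
#' 50 ms minimum saccade separation for the offline variant, and a
#' robust-OKN rule of two validated slow phases.
#'
#' @param mode `"offline"` (full sampling rate, blink masking, 50 ms
#'   saccade merging) or `"live"` (frame-rate analysis, no blink masking,
#'   no merging). Mode only changes the defaults marked below.
#' @param noise_window_frames display frames used exclusively for noise
#'   estimation (default 34).
#' @param frame_rate_hz display refresh rate (default 120).
#' @param lambda_noise noise-threshold multiplier (default 7).
#' @param smooth_window_samples moving-average width for slow-phase
#'   velocity estimation (default 5).
#' @param trim_ms slow-phase trimming at each end, two screen refreshes
#'   (default `2 * 1000 / frame_rate_hz`, ~17 ms).
#' @param sp_velocity_threshold_dps minimum absolute slow-phase mean
#'   velocity in deg/s. No canonical value exists for this threshold; the
#'   default 0.5 deg/s sits well below the expected slow-phase speed
#'   (gain times stimulus speed) and well above fixational drift. Sanity
#'   bound: must not exceed twice the stimulus speed.
#' @param sp_velocity_estimator `"endpoint"` (displacement of the smoothed
#'   segment over its duration, default) or `"mean"` (mean of the finite
#'   velocity samples in the segment).
#' @param robust_count validated slow phases required to call the stimulus
#'   seen (default 2).
#' @param robust_unit `"slow_phases"` (default) or `"pairs"`: whether the
#'   robust rule counts validated slow phases or quick/slow-phase pairs.
#' @param timeout_s trial timeout (default 4).
#' @param blink_buffer_ms blink-mask buffer, offline only (default 50).
#' @param min_saccade_duration_ms minimum quick-phase duration; mode
#'   default: 6 ms offline (6 samples at 1000 Hz), two frames live.
#' @param min_saccade_separation_ms merge threshold; mode default: 50
#'   offline, 0 live.
#' @param binocular_required binocular-overlap criterion (default TRUE).
#' @param live_full_rate if `TRUE`, [run_live()] analyses every
#'   eye-tracker sample instead of one sample per display frame (the
#'   noise window still spans the same 283 ms). Default `FALSE`: the
#'   frame-decimated interpretation.
#' @return an object of class `detector_config` (a named list).
#' @export
detector_config <- function(mode = c("offline", "live"),
                            noise_window_frames = 34L,
                            frame_rate_hz = 120,
                            lambda_noise = 7,
                            smooth_window_samples = 5L,
                            trim_ms = 2 * 1000 / frame_rate_hz,
                            sp_velocity_threshold_dps = 0.5,
                            sp_velocity_estimator = c("endpoint", "mean"),
                            robust_count = 2L,
                            robust_unit = c("slow_phases", "pairs"),
                            timeout_s = 4.0,
                            blink_buffer_ms = 50,
                            min_saccade_duration_ms = NULL,
                            min_saccade_separation_ms = NULL,
                            binocular_required = TRUE,
                            live_full_rate = FALSE) {
  mode <- match.arg(mode)
  if (is.null(min_saccade_duration_ms)) {
    min_saccade_duration_ms <- if (mode == "offline") 6 else 2000 / frame_rate_hz
  }
  if (is.null(min_saccade_separation_ms)) {
    min_saccade_separation_ms <- if (mode == "offline") 50 else 0
  }
  structure(list(
    mode = mode,
    noise_window_frames = as.integer(noise_window_frames),
    frame_rate_hz = frame_rate_hz,
    lambda_noise = lambda_noise,
    smooth_window_samples = as.integer(smooth_window_samples),
    trim_ms = trim_ms,
    sp_velocity_threshold_dps = sp_velocity_threshold_dps,
    sp_velocity_estimator = match.arg(sp_velocity_estimator),
    robust_count = as.integer(robust_count),
    robust_unit = match.arg(robust_unit),
    timeout_s = timeout_s,
    blink_buffer_ms = blink_buffer_ms,
    min_saccade_duration_ms = min_saccade_duration_ms,
    min_saccade_separation_ms = min_saccade_separation_ms,
    binocular_required = isTRUE(binocular_required),
    live_full_rate = isTRUE(live_full_rate)),
    class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf("<detector_config> mode=%s lambda=%g noise_window=%d frames @ %g Hz\n",
              x$mode, x$lambda_noise, x$noise_window_frames, x$frame_rate_hz))
  cat(sprintf("  SP: |v| >= %g deg/s (%s), trim %.1f ms, smooth %d samples; robust_count=%d\n",
              x$sp_velocity_threshold_dps, x$sp_velocity_estimator, x$trim_ms,
              x$smooth_window_samples, x$robust_count))
  invisible(x)
}

# Duration of the noise-estimation window in ms.
noise_window_ms <- function(config) {
  config$noise_window_frames * 1000 / config$frame_rate_hz
}
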