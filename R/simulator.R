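# Synthetic gaze and observer generation: labelled saw-tooth OKN traces,
# fixation (no-OKN) traces, and virtual observers whose per-trial OKN
# probability follows a ground-truth Weibull function of contrast. Every
# generator is deterministic given its seed and every trace carries its
# ground-truth label and event list, so detection performance can be
# scored against construction rather than against another detector.

#' Parameters of the synthetic OKN/fixation trace generator
#'
#' @param gain slow-phase velocity as a fraction of stimulus velocity
#'   (default 0.76, the canonical OKN gain); must lie in (0, 1.5].
#' @param saccade_amplitude_deg quick-phase amplitude (default 1): with
#'   the default gain and a 2.3 deg/s stimulus this reproduces the
#'   ~0.6 s quick-phase cycle of stare-OKN, so a robust response (two
#'   validated slow phases) is detectable by roughly 1.5-2 s.
#' @param saccade_duration_ms quick-phase duration (default 30).
#' @param position_noise_sd_deg total marginal SD of the per-eye sensor
#'   noise (default 0.05). Video-tracker noise is mostly slow
#'   pupil-estimation wander with a little per-sample jitter; see
#'   `noise_wander_ms` and `noise_jitter_fraction`.
#' @param noise_wander_ms correlation length of the slow wander component
#'   (default 200).
#' @param noise_jitter_fraction fraction of the noise variance in white
#'   per-sample jitter (default 0.05).
#' @param onset_latency_ms delay between stimulus onset and the first
#'   slow phase (default 250); optokinetic tracking builds up over a few
#'   hundred milliseconds, during which gaze is fixation-like. This is
#'   also the period the live detector reserves for noise assessment.
#' @param blink_rate_hz expected blinks per second (default 0.1).
#' @param blink_duration_ms blink length (default 150).
#' @param binocular_disparity_noise_deg SD of the slowly varying
#'   independent per-eye offset (default 0.02).
#' @param fixation_drift_dps slow drift speed of fixation traces, well
#'   below any slow-phase threshold (default 0.1).
#' @param seed default seed for generators receiving this object; `NULL`
#'   uses the ambient RNG stream.
#' @return object of class `okn_gen_params`.
#' @export
okn_gen_params <- function(gain = 0.76,
                           saccade_amplitude_deg = 1.0,
                           saccade_duration_ms = 30,
                           position_noise_sd_deg = 0.05,
                           noise_wander_ms = 200,
                           noise_jitter_fraction = 0.05,
                           onset_latency_ms = 250,
                           blink_rate_hz = 0.1,
                           blink_duration_ms = 150,
                           binocular_disparity_noise_deg = 0.02,
                           fixation_drift_dps = 0.1,
                           seed = NULL) {
  if (!(gain > 0 && gain <= 1.5)) {
    stop_okncs("gain must lie in (0, 1.5]", "okncs_config_error")
  }
  stopifnot(position_noise_sd_deg >= 0, blink_rate_hz >= 0,
            binocular_disparity_noise_deg >= 0, saccade_amplitude_deg > 0,
            saccade_duration_ms > 0, onset_latency_ms >= 0,
            noise_jitter_fraction >= 0, noise_jitter_fraction <= 1)
  structure(list(gain = gain,
                 saccade_amplitude_deg = saccade_amplitude_deg,
                 saccade_duration_ms = saccade_duration_ms,
                 position_noise_sd_deg = position_noise_sd_deg,
                 noise_wander_ms = noise_wander_ms,
                 noise_jitter_fraction = noise_jitter_fraction,
                 onset_latency_ms = onset_latency_ms,
                 blink_rate_hz = blink_rate_hz,
                 blink_duration_ms = blink_duration_ms,
                 binocular_disparity_noise_deg = binocular_disparity_noise_deg,
                 fixation_drift_dps = fixation_drift_dps,
                 seed = seed),
            class = "okn_gen_params")
}

# band-limited noise: white Gaussian smoothed by a boxcar of the given
# correlation length, rescaled to the requested marginal SD
band_limited_noise <- function(n, sd, correlation_ms, rate_hz) {
  if (sd <= 0) return(numeric(n))
  k <- max(1L, round(correlation_ms * rate_hz / 1000))
  pad <- stats::rnorm(n + 2L * k)
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2L)
  sm <- sm[(k + 1L):(k + n)]
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (!is.finite(s) || s == 0) return(rep(0, n))
  sm / s * sd
}

# core saw-tooth construction; returns positions and the ground-truth
# event table for a noiseless monocular signal. Tracking starts after the
# onset latency; gaze is stationary before it.
sawtooth_signal <- function(t_ms, direction, sp_speed_dps, amplitude,
                            qp_duration_ms, start_fraction,
                            onset_latency_ms = 0) {
  n <- length(t_ms)
  x <- numeric(n)
  events <- NULL
  half <- amplitude / 2
  pos <- direction * (-half + start_fraction * amplitude)
  t_cur <- t_ms[1L] + onset_latency_ms
  t_end <- t_ms[n]
  if (onset_latency_ms > 0) {
    x[t_ms < t_cur] <- pos
    events <- data.frame(type = "fixation", t_start = t_ms[1L],
                         t_end = min(t_cur, t_end), velocity = 0)
    if (t_cur >= t_end) return(list(x = x, events = events))
  }
  repeat {
    # slow phase: drift with the stimulus until the ramp completes
    sp_len_ms <- (half - pos * direction) / abs(sp_speed_dps) * 1000
    sp_end <- t_cur + sp_len_ms
    idx <- which(t_ms >= t_cur & t_ms < sp_end)
    if (length(idx)) x[idx] <- pos + sp_speed_dps * (t_ms[idx] - t_cur) / 1000
    events <- rbind(events, data.frame(type = "sp", t_start = t_cur,
                                       t_end = min(sp_end, t_end),
                                       velocity = sp_speed_dps))
    if (sp_end >= t_end) break
    # quick phase: smooth raised-cosine reset against the drift
    qp_end <- sp_end + qp_duration_ms
    idx <- which(t_ms >= sp_end & t_ms < qp_end)
    x_at <- direction * half
    if (length(idx)) {
      u <- (t_ms[idx] - sp_end) / qp_duration_ms
      x[idx] <- x_at - direction * amplitude * (1 - cos(pi * u)) / 2
    }
    events <- rbind(events, data.frame(type = "qp", t_start = sp_end,
                                       t_end = min(qp_end, t_end),
                                       velocity = -direction * amplitude /
                                         (qp_duration_ms / 1000)))
    if (qp_end >= t_end) break
    pos <- -direction * half
    t_cur <- qp_end
  }
  list(x = x, events = events)
}

insert_blinks <- function(samples, gen, duration_s, rate_hz) {
  n_blinks <- stats::rpois(1L, gen$blink_rate_hz * duration_s)
  if (n_blinks == 0L) return(samples)
  starts <- sort(stats::runif(n_blinks, 0, duration_s * 1000 -
                                gen$blink_duration_ms))
  for (b in starts) {
    idx <- which(samples$t >= b & samples$t < b + gen$blink_duration_ms)
    samples$x_left[idx] <- NA_real_
    samples$x_right[idx] <- NA_real_
    samples$y_left[idx] <- NA_real_
    samples$y_right[idx] <- NA_real_
    samples$pupil_left[idx] <- 0
    samples$pupil_right[idx] <- 0
  }
  samples
}

binocularize <- function(t_ms, signal, gen, rate_hz, duration_s) {
  n <- length(t_ms)
  sd_jitter <- gen$position_noise_sd_deg * sqrt(gen$noise_jitter_fraction)
  sd_wander <- gen$position_noise_sd_deg * sqrt(1 - gen$noise_jitter_fraction)
  sensor_noise <- function() {
    band_limited_noise(n, sd_wander, gen$noise_wander_ms, rate_hz) +
      stats::rnorm(n, 0, sd_jitter)
  }
  eye <- function() {
    signal + sensor_noise() +
      band_limited_noise(n, gen$binocular_disparity_noise_deg, 200, rate_hz)
  }
  samples <- data.frame(
    t = t_ms,
    x_left = eye(),
    y_left = sensor_noise(),
    pupil_left = 1000 + stats::rnorm(n, 0, 5),
    x_right = eye(),
    y_right = sensor_noise(),
    pupil_right = 1000 + stats::rnorm(n, 0, 5))
  samples$pupil_left <- pmax(samples$pupil_left, 1)
  samples$pupil_right <- pmax(samples$pupil_right, 1)
  insert_blinks(samples, gen, duration_s, rate_hz)
}

#' Synthesize a saw-tooth OKN gaze trace (ground-truth label: OKN present)
#'
#' Slow phases drift with the stimulus at `gain * velocity_dps`; quick
#' phases are smooth raised-cosine resets of the configured amplitude and
#' duration against the drift. Both eyes share the saw-tooth signal plus
#' independent band-limited sensor noise and a slow disparity offset;
#' blinks are inserted as track-lost runs at the configured rate.
#'
#' @param stimulus a [stimulus_spec()].
#' @param gen an [okn_gen_params()].
#' @param duration_s trace duration (default: the stimulus timeout).
#' @param rate_hz sampling rate (default 1000).
#' @param seed seed (default: `gen$seed`); `NULL` uses the ambient RNG.
#' @return a [gaze_trace()]; `meta$label` is `"okn"` and `meta$truth`
#'   holds the generated event table and slow-phase velocity.
#' @export
synth_okn_trace <- function(stimulus, gen = okn_gen_params(),
                            duration_s = stimulus$duration_max_s,
                            rate_hz = 1000, seed = gen$seed) {
  stopifnot(duration_s > 0)
  with_seed(seed, {
    t_ms <- seq(0, duration_s * 1000 - 1000 / rate_hz, by = 1000 / rate_hz)
    sp_speed <- gen$gain * stimulus$velocity_dps * stimulus$direction
    sig <- sawtooth_signal(t_ms, stimulus$direction, sp_speed,
                           gen$saccade_amplitude_deg,
                           gen$saccade_duration_ms,
                           start_fraction = stats::runif(1L),
                           onset_latency_ms = gen$onset_latency_ms)
    samples <- binocularize(t_ms, sig$x, gen, rate_hz, duration_s)
    gaze_trace(samples, rate_hz = rate_hz,
               meta = list(label = "okn",
                           truth = list(events = sig$events,
                                        sp_velocity_dps = sp_speed,
                                        gen = gen, stimulus = stimulus)))
  })
}

#' Synthesize a fixation gaze trace (ground-truth label: OKN absent)
#'
#' Stationary gaze plus band-limited sensor noise and a slow drift well
#' below any slow-phase velocity threshold; optional blinks.
#'
#' @param gen an [okn_gen_params()].
#' @param duration_s trace duration in s.
#' @param rate_hz sampling rate.
#' @param seed seed (default `gen$seed`); `NULL` uses the ambient RNG.
#' @return a [gaze_trace()] with `meta$label = "fixation"`.
#' @export
synth_fixation_trace <- function(gen = okn_gen_params(), duration_s = 4,
                                 rate_hz = 1000, seed = gen$seed) {
  stopifnot(duration_s > 0)
  with_seed(seed, {
    t_ms <- seq(0, duration_s * 1000 - 1000 / rate_hz, by = 1000 / rate_hz)
    drift_dir <- sample(c(-1, 1), 1L)
    signal <- drift_dir * gen$fixation_drift_dps * t_ms / 1000
    signal <- signal - mean(signal)
    samples <- binocularize(t_ms, signal, gen, rate_hz, duration_s)
    gaze_trace(samples, rate_hz = rate_hz,
               meta = list(label = "fixation",
                           truth = list(events = NULL,
                                        drift_dps = drift_dir *
                                          gen$fixation_drift_dps,
                                        gen = gen)))
  })
}

#' Virtual psychometric observer
#'
#' A table of ground-truth Weibull parameters per spatial frequency plus
#' the trace-generation parameters. The observer responds to a stimulus
#' with whole-trial OKN presence drawn from its psychometric function.
#'
#' @param true_params data frame with columns `sf_cpd`, `m`
#'   (natural-log threshold) and `w` (width); thresholds must lie inside
#'   the contrast ladder span.
#' @param gen an [okn_gen_params()].
#' @param label free-form condition label.
#' @param ladder the ladder whose span constrains the thresholds.
#' @return object of class `virtual_observer`.
#' @export
virtual_observer <- function(true_params, gen = okn_gen_params(),
                             label = "observer", ladder = contrast_ladder()) {
  stopifnot(all(c("sf_cpd", "m", "w") %in% names(true_params)))
  ct <- exp(true_params$m)
  if (any(ct < min(ladder) | ct > max(ladder))) {
    stop_okncs("observer thresholds must lie within the contrast ladder span",
               "okncs_config_error")
  }
  structure(list(true_params = true_params, gen = gen, label = label),
            class = "virtual_observer")
}

#' @export
print.virtual_observer <- function(x, ...) {
  cat(sprintf("<virtual_observer> %s: %d spatial frequencies\n", x$label,
              nrow(x$true_params)))
  tp <- x$true_params
  tp$ct <- exp(tp$m)
  tp$cs <- exp(-tp$m)
  print(tp, digits = 3)
  invisible(x)
}

#' Build a virtual observer from a ground-truth CSF
#'
#' Thresholds per spatial frequency derive from a log-parabola CSF
#' (`CT(SF) = 1 / CS(SF)`); the psychometric width is constant across
#' frequencies.
#'
#' @param csf a [csf_params()] ground truth.
#' @param slope psychometric slope (default 3, a mid-grid value); the
#'   width is `w = c / slope`.
#' @param sf_set spatial frequencies.
#' @param gen an [okn_gen_params()].
#' @param label condition label.
#' @return a [virtual_observer()].
#' @export
observer_from_csf <- function(csf, slope = 3,
                              sf_set = c(0.7, 1.5, 2.6, 3.7, 5.2, 6.5),
                              gen = okn_gen_params(), label = "observer") {
  log10_cs <- logparabola(sf_set, csf)
  m <- -log(10) * log10_cs
  virtual_observer(data.frame(sf_cpd = sf_set, m = m,
                              w = weibull_c() / slope),
                   gen = gen, label = label)
}

#' Virtual observers for a defocus series
#'
#' Ground-truth CSFs emulating increasing optical defocus: peak
#' sensitivity and peak spatial frequency both fall with lens power, so
#' sensitivity losses concentrate at high spatial frequencies.
#'
#' @param gen an [okn_gen_params()] shared by all conditions.
#' @param slope psychometric slope for every condition.
#' @return named list of [virtual_observer()]s for 0 D, +1.5 D, +2.0 D
#'   and +2.5 D, each with a `true_csf` attribute.
#' @export
defocus_observers <- function(gen = okn_gen_params(), slope = 3) {
  presets <- list(
    "0D"    = csf_params(gamma_max = 160, sf_max = 1.8, beta = 3.2),
    "+1.5D" = csf_params(gamma_max = 80,  sf_max = 1.2, beta = 2.8),
    "+2.0D" = csf_params(gamma_max = 45,  sf_max = 1.0, beta = 2.6),
    "+2.5D" = csf_params(gamma_max = 25,  sf_max = 0.8, beta = 2.4))
  out <- lapply(names(presets), function(nm) {
    ob <- observer_from_csf(presets[[nm]], slope = slope, gen = gen,
                            label = nm)
    attr(ob, "true_csf") <- presets[[nm]]
    ob
  })
  stats::setNames(out, names(presets))
}

#' Simulate one observed trial
#'
#' Draws whole-trial OKN presence as a Bernoulli outcome with probability
#' given by the observer's psychometric function at the stimulus
#' contrast, then emits a matching synthetic trace (saw-tooth OKN or
#' fixation).
#'
#' @param observer a [virtual_observer()].
#' @param stimulus a [stimulus_spec()] whose `sf_cpd` appears in the
#'   observer's table.
#' @param seed seed; `NULL` uses the ambient RNG.
#' @param rate_hz sampling rate of the emitted trace.
#' @return list with `trace` (a [gaze_trace()]), `label` (`"okn"` or
#'   `"fixation"`) and `p_okn` (the generating probability).
#' @export
observe_trial <- function(observer, stimulus, seed = NULL, rate_hz = 1000) {
  row <- which(abs(observer$true_params$sf_cpd - stimulus$sf_cpd) < 1e-9)
  if (length(row) != 1L) {
    stop_okncs(sprintf("observer has no ground truth at %.3g cpd",
                       stimulus$sf_cpd), "okncs_config_error")
  }
  params <- psychometric_params(observer$true_params$m[row],
                                observer$true_params$w[row])
  p <- weibull_psi(stimulus$contrast, params)
  with_seed(seed, {
    present <- stats::runif(1L) < p
    trace <- if (present) {
      synth_okn_trace(stimulus, observer$gen, rate_hz = rate_hz, seed = NULL)
    } else {
      synth_fixation_trace(observer$gen, duration_s = stimulus$duration_max_s,
                           rate_hz = rate_hz, seed = NULL)
    }
    list(trace = trace, label = if (present) "okn" else "fixation", p_okn = p)
  })
}

#' Generate a labelled corpus of OKN and fixation traces
#'
#' @param n_okn,n_fixation class sizes.
#' @param stimulus a [stimulus_spec()] for the positive class.
#' @param gen an [okn_gen_params()].
#' @param seed master seed.
#' @param rate_hz sampling rate.
#' @return list with `traces` (list of [gaze_trace()]) and `manifest`
#'   (data frame `id`, `label`, `direction`).
#' @export
synth_corpus <- function(n_okn = 100L, n_fixation = 100L,
                         stimulus = stimulus_spec(sf_cpd = 2.6,
                                                  contrast = 0.5),
                         gen = okn_gen_params(), seed = 1L,
                         rate_hz = 1000) {
  with_seed(seed, {
    traces <- vector("list", n_okn + n_fixation)
    label <- character(n_okn + n_fixation)
    direction <- numeric(n_okn + n_fixation)
    for (i in seq_len(n_okn)) {
      dir_i <- sample(c(-1, 1), 1L)
      stim_i <- stimulus
      stim_i$direction <- dir_i
      traces[[i]] <- synth_okn_trace(stim_i, gen, rate_hz = rate_hz,
                                     seed = NULL)
      label[i] <- "okn"
      direction[i] <- dir_i
    }
    for (j in seq_len(n_fixation)) {
      i <- n_okn + j
      traces[[i]] <- synth_fixation_trace(gen,
                                          duration_s = stimulus$duration_max_s,
                                          rate_hz = rate_hz, seed = NULL)
      label[i] <- "fixation"
      direction[i] <- stimulus$direction
    }
    list(traces = traces,
         manifest = data.frame(id = seq_along(traces), label = label,
                               direction = direction))
  })
}
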