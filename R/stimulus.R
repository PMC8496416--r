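# Stimulus bookkeeping: screen geometry, angular field of view, the
# log-spaced contrast ladder, trial scheduling and optical-demand helpers.

#' Screen geometry
#'
#' @param resolution_px integer pair, horizontal and vertical pixels.
#' @param pixel_pitch_mm physical pixel pitch in mm.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @return an object of class `screen_geometry`.
#' @examples
#' screen_geometry()  # 1920 x 1200 at 0.252 mm pitch, 75 cm
#' @export
screen_geometry <- function(resolution_px = c(1920L, 1200L),
                            pixel_pitch_mm = 0.252,
                            viewing_distance_cm = 75) {
  stopifnot(all(resolution_px > 0), pixel_pitch_mm > 0,
            viewing_distance_cm > 0)
  structure(list(resolution_px = resolution_px,
                 pixel_pitch_mm = pixel_pitch_mm,
                 viewing_distance_cm = viewing_distance_cm),
            class = "screen_geometry")
}

#' Angular field of view of a screen
#'
#' `angle = 2 * atan(extent / (2 * distance))` per axis.
#'
#' @param geometry a [screen_geometry()].
#' @return named numeric vector `c(horizontal, vertical)` in degrees.
#' @examples
#' round(field_of_view(screen_geometry()))  # ~36 and ~23 degrees
#' @export
field_of_view <- function(geometry) {
  extent_mm <- geometry$resolution_px * geometry$pixel_pitch_mm
  d_mm <- geometry$viewing_distance_cm * 10
  ang <- 2 * atan(extent_mm / (2 * d_mm)) * 180 / pi
  stats::setNames(ang, c("horizontal", "vertical"))
}

#' Log-spaced contrast ladder
#'
#' The admissible Michelson contrast levels for stimulus display and for
#' the QUEST+ threshold space: `n_levels` values log-uniformly spaced
#' between `lo` and `hi` with exact endpoints.
#'
#' @param n_levels number of levels (default 39).
#' @param lo,hi lowest and highest contrast as fractions in (0, 1].
#' @return ascending numeric vector of length `n_levels`.
#' @export
contrast_ladder <- function(n_levels = 39L, lo = 0.0003, hi = 0.66) {
  if (!(lo > 0 && lo < hi && hi <= 1)) {
    stop_okncs("contrast ladder needs 0 < lo < hi <= 1", "okncs_config_error")
  }
  exp(seq(log(lo), log(hi), length.out = n_levels))
}

#' Accommodative demand of a viewing distance
#'
#' @param distance_cm viewing distance in cm.
#' @return demand in diopters, `100 / distance_cm`.
#' @examples
#' accommodative_demand(75)  # 1.33 D
#' @export
accommodative_demand <- function(distance_cm) {
  stopifnot(distance_cm > 0)
  100 / distance_cm
}

#' Drifting-grating stimulus specification
#'
#' @param sf_cpd spatial frequency in cycles per degree.
#' @param contrast Michelson contrast fraction in (0, 1].
#' @param direction drift direction: `+1` (rightward), `-1` (leftward), or
#'   the labels `"temporal"` / `"nasal"` (mapped assuming right-eye
#'   stimulation: temporal = rightward).
#' @param velocity_dps drift speed in deg/s (default 2.3).
#' @param duration_max_s presentation timeout in s (default 4).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(sf_cpd, contrast, direction = 1,
                          velocity_dps = 2.3, duration_max_s = 4.0) {
  if (is.character(direction)) {
    direction <- switch(match.arg(direction, c("temporal", "nasal")),
                        temporal = 1, nasal = -1)
  }
  stopifnot(direction %in% c(-1, 1), sf_cpd > 0,
            contrast > 0, contrast <= 1, velocity_dps > 0)
  structure(list(sf_cpd = sf_cpd, contrast = contrast, direction = direction,
                 velocity_dps = velocity_dps, duration_max_s = duration_max_s),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %.2g cpd, contrast %.4g, %s at %.2g deg/s, timeout %gs\n",
    x$sf_cpd, x$contrast, if (x$direction > 0) "rightward" else "leftward",
    x$velocity_dps, x$duration_max_s))
  invisible(x)
}

#' Experiment plan
#'
#' Metadata describing one measurement session: the spatial frequencies
#' tested, the number of trials per frequency (drift directions balanced),
#' and inter-trial fixation-cross bookkeeping.
#'
#' @param sf_set spatial frequencies in cpd.
#' @param n_trials_per_sf trials per spatial frequency (default 64).
#' @param defocus_conditions condition labels (metadata only).
#' @param ladder the contrast ladder used for stimulus selection.
#' @param velocity_dps,timeout_s stimulus motion parameters.
#' @param cross_size_deg,cross_duration_s inter-trial cross metadata.
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(sf_set = c(0.7, 1.5, 2.6, 3.7, 5.2, 6.5),
                            n_trials_per_sf = 64L,
                            defocus_conditions = "0D",
                            ladder = contrast_ladder(),
                            velocity_dps = 2.3, timeout_s = 4.0,
                            cross_size_deg = 1.25, cross_duration_s = 1.3) {
  stopifnot(all(sf_set > 0), n_trials_per_sf > 0)
  structure(list(sf_set = sf_set, n_trials_per_sf = as.integer(n_trials_per_sf),
                 defocus_conditions = defocus_conditions, ladder = ladder,
                 velocity_dps = velocity_dps, timeout_s = timeout_s,
                 cross_size_deg = cross_size_deg,
                 cross_duration_s = cross_duration_s),
            class = "experiment_plan")
}

#' Ordered trial schedule for an experiment plan
#'
#' Spatial-frequency blocks in seeded-random order; within each block the
#' two drift directions are assigned in (as near as possible) equal counts
#' and shuffled. Contrast levels are left blank: they are chosen live by
#' the adaptive staircase.
#'
#' @param plan an [experiment_plan()].
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return data frame with columns `trial`, `sf_cpd`, `direction`.
#' @export
plan_experiment <- function(plan, seed = 1L) {
  n <- plan$n_trials_per_sf
  half <- n %/% 2L
  if (n %% 2L == 1L) {
    warning(sprintf(
      "odd n_trials_per_sf = %d: directions split %d rightward / %d leftward",
      n, n - half, half))
  }
  with_seed(seed, {
    sf_order <- if (length(plan$sf_set) == 1L) plan$sf_set
    else sample(plan$sf_set)
    blocks <- lapply(sf_order, function(sf) {
      dirs <- sample(c(rep(1, n - half), rep(-1, half)))
      data.frame(sf_cpd = sf, direction = dirs)
    })
    out <- do.call(rbind, blocks)
    out <- cbind(trial = seq_len(nrow(out)), out)
    out
  })
}
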