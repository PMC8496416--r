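# QUEST+ Bayesian adaptive contrast selection over a Weibull psychometric
# model. The posterior lives on a (threshold x slope) grid; the next
# contrast is the ladder level minimizing the expected posterior entropy
# over the two possible outcomes. The module itself is fully deterministic;
# randomness lives only in the simulated observers that consume it.

#' Initialize a QUEST+ state
#'
#' The threshold grid is identified with the contrast ladder (the
#' displayable set) and the slope grid defaults to 0.5 to 5.5 in steps of
#' 0.5. Guess and lapse rates are fixed at zero.
#'
#' @param ladder ascending contrast levels in (0, 1]
#'   (default [contrast_ladder()], 39 levels).
#' @param slope_grid candidate psychometric slopes
#'   (default `seq(0.5, 5.5, by = 0.5)`).
#' @param prior prior mass over the `length(ladder) x length(slope_grid)`
#'   grid (matrix or vector in grid order), or `NULL` for uniform; it is
#'   renormalized.
#' @return An object of class `quest_state`: list with `ladder`,
#'   `slope_grid`, `posterior` (matrix, rows = thresholds, columns =
#'   slopes, summing to 1), `lik` (precomputed P(seen) array,
#'   contrast x threshold x slope) and `history`.
#' @export
quest_init <- function(ladder = contrast_ladder(),
                       slope_grid = seq(0.5, 5.5, by = 0.5),
                       prior = NULL) {
  if (any(diff(ladder) <= 0) || any(ladder <= 0) || any(ladder > 1)) {
    stop_okncs("contrast ladder must be strictly increasing within (0, 1]",
               "okncs_config_error")
  }
  nt <- length(ladder)
  ns <- length(slope_grid)
  if (is.null(prior)) {
    posterior <- matrix(1 / (nt * ns), nt, ns)
  } else {
    posterior <- matrix(as.numeric(prior), nt, ns)
    if (any(posterior < 0) || sum(posterior) <= 0) {
      stop_okncs("prior must be non-negative with positive mass",
                 "okncs_config_error")
    }
    posterior <- posterior / sum(posterior)
  }
  # P(seen | contrast i, threshold j, slope k), Weibull with zero asymptotes
  cc <- weibull_c()
  lik <- array(NA_real_, dim = c(nt, nt, ns))
  logx <- log(ladder)
  for (k in seq_len(ns)) {
    w <- cc / slope_grid[k]
    lik[, , k] <- 1 - exp(log(0.5) *
                            exp(cc * outer(logx, logx, "-") / w))
  }
  structure(list(ladder = ladder, slope_grid = slope_grid,
                 posterior = posterior, lik = lik,
                 history = data.frame(contrast = numeric(0),
                                      outcome = character(0))),
            class = "quest_state")
}

#' Probability of "seen" under one grid hypothesis
#'
#' Evaluates the zero-asymptote cumulative Weibull at `contrast` for a
#' candidate threshold (a ladder level) and slope: the likelihood that
#' QUEST+ attaches to a "seen" outcome in that grid cell.
#'
#' @param contrast stimulus contrast in (0, 1].
#' @param threshold_candidate candidate threshold contrast in (0, 1].
#' @param slope_candidate candidate slope, `> 0`.
#' @return probability of a "seen" outcome.
#' @export
outcome_likelihood <- function(contrast, threshold_candidate,
                               slope_candidate) {
  stopifnot(contrast > 0, threshold_candidate > 0, slope_candidate > 0)
  weibull_psi(contrast,
              psychometric_params(m = log(threshold_candidate),
                                  w = weibull_c() / slope_candidate))
}

#' Bayesian update of a QUEST+ state with one trial outcome
#'
#' Multiplies the posterior by the outcome likelihood in every grid cell
#' and renormalizes. Updates commute: any permutation of a trial sequence
#' yields the same posterior.
#'
#' @param state a [quest_init()] state.
#' @param contrast the presented contrast; must be a ladder level.
#' @param outcome `"seen"` or `"not_seen"`.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, contrast, outcome) {
  outcome <- match.arg(outcome, c("seen", "not_seen"))
  i <- match_ladder(state$ladder, contrast)
  p_seen <- state$lik[i, , ]
  lik <- if (outcome == "seen") p_seen else 1 - p_seen
  post <- state$posterior * lik
  z <- sum(post)
  if (z <= 0) {
    stop_okncs("posterior mass vanished (outcome impossible under the grid)",
               "okncs_data_error")
  }
  state$posterior <- post / z
  state$history <- rbind(state$history,
                         data.frame(contrast = contrast, outcome = outcome))
  state
}

match_ladder <- function(ladder, contrast) {
  i <- which(abs(log(ladder) - log(contrast)) < 1e-9)
  if (length(i) != 1L) {
    stop_okncs(sprintf("contrast %.6g is not a ladder level", contrast),
               "okncs_config_error")
  }
  i
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select the next contrast by expected-entropy minimization
#'
#' For each candidate ladder level x, computes the predictive probability
#' of each outcome and the entropy of the posterior updated by that
#' outcome; returns the level minimizing the expected posterior entropy,
#' breaking ties toward the lower contrast.
#'
#' @param state a `quest_state`.
#' @param details if `TRUE`, return a list with the per-level expected
#'   entropies as well.
#' @return the selected contrast (or a list when `details = TRUE`).
#' @export
quest_next_contrast <- function(state, details = FALSE) {
  nt <- length(state$ladder)
  post <- as.vector(state$posterior)
  eh <- vapply(seq_len(nt), function(i) {
    p_seen_cells <- as.vector(state$lik[i, , ])
    p1 <- sum(post * p_seen_cells)
    p0 <- 1 - p1
    h1 <- if (p1 > 0) entropy_nats(post * p_seen_cells / p1) else 0
    h0 <- if (p0 > 0) entropy_nats(post * (1 - p_seen_cells) / p0) else 0
    p1 * h1 + p0 * h0
  }, numeric(1))
  pick <- which(eh <= min(eh) + 1e-12)[1L]
  if (details) list(contrast = state$ladder[pick], expected_entropy = eh)
  else state$ladder[pick]
}

#' Posterior summary of a QUEST+ state
#'
#' Posterior mean and mode of the natural-log threshold and of the slope,
#' with equal-tail marginal credible intervals.
#'
#' @param state a `quest_state`.
#' @param level credible-interval coverage (default 0.95).
#' @return list with `log_threshold` and `slope`, each holding `mean`,
#'   `mode` and `ci`.
#' @export
quest_estimate <- function(state, level = 0.95) {
  marg_t <- rowSums(state$posterior)
  marg_s <- colSums(state$posterior)
  logl <- log(state$ladder)
  ci <- function(values, mass) {
    cum <- cumsum(mass)
    lo <- values[which(cum >= (1 - level) / 2)[1L]]
    hi <- values[which(cum >= 1 - (1 - level) / 2)[1L]]
    c(lo, hi)
  }
  joint_mode <- which(state$posterior == max(state$posterior),
                      arr.ind = TRUE)[1L, ]
  list(log_threshold = list(mean = sum(marg_t * logl),
                            mode = logl[joint_mode[[1L]]],
                            ci = ci(logl, marg_t)),
       slope = list(mean = sum(marg_s * state$slope_grid),
                    mode = state$slope_grid[joint_mode[[2L]]],
                    ci = ci(state$slope_grid, marg_s)))
}

#' Serialize a QUEST+ state to a human-readable audit log
#'
#' Writes the grids, the full posterior and the trial history as pretty
#' JSON, so a run can be audited or replayed.
#'
#' @param state a `quest_state`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
quest_serialize <- function(state, path) {
  jsonlite::write_json(
    list(ladder = state$ladder, slope_grid = state$slope_grid,
         posterior = state$posterior, history = state$history,
         estimate = quest_estimate_safe(state)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

quest_estimate_safe <- function(state) {
  if (nrow(state$history) == 0L) NULL else quest_estimate(state)
}

#' @export
print.quest_state <- function(x, ...) {
  est <- quest_estimate(x)
  cat(sprintf(
    "<quest_state> %d trials; posterior entropy %.3f nats; mode: CT=%.4g, slope=%.2g\n",
    nrow(x$history), entropy_nats(as.vector(x$posterior)),
    exp(est$log_threshold$mode), est$slope$mode))
  invisible(x)
}
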