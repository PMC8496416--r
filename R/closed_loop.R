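# End-to-end closed-loop simulation: QUEST+ contrast selection, synthetic
# trial observation, OKN detection, psychometric fitting per spatial
# frequency, and CSF fitting across frequencies.

#' Run a full closed-loop contrast-sensitivity measurement in silico
#'
#' For each spatial frequency of the plan, runs `n_trials_per_sf` trials:
#' QUEST+ proposes a contrast, the virtual observer emits a synthetic
#' gaze trace, the detector decides seen/not-seen, and the outcome feeds
#' back into QUEST+. The accumulated outcome table is then fitted with
#' the cumulative Weibull psychometric function; finally the per-SF
#' sensitivities are fitted with the log-parabola CSF.
#'
#' @param observer a [virtual_observer()].
#' @param plan an [experiment_plan()].
#' @param config a [detector_config()] for the in-loop detector.
#' @param seed master seed; the whole run is deterministic given it.
#' @param detector `"live"` (default; causal frame-rate detection),
#'   `"offline"` (full-rate post-hoc detection), or `"oracle"` (the
#'   generator's ground-truth label stands in for detection, an upper
#'   bound on achievable recovery).
#' @param rate_hz sampling rate of the synthetic recordings.
#' @return An object of class `okn_experiment`: list with `trials` (audit
#'   log: sf, trial, contrast, label, decision, decision time), `per_sf`
#'   (per-frequency outcome table, `psychfit`, threshold and
#'   sensitivity), `cs_table`, `csf` (a `csffit`), `plan`, `observer` and
#'   `seed`.
#' @export
run_closed_loop <- function(observer, plan = experiment_plan(),
                            config = detector_config("live"),
                            seed = 1L,
                            detector = c("live", "offline", "oracle"),
                            rate_hz = 1000) {
  detector <- match.arg(detector)
  schedule <- plan_experiment(plan, seed)
  with_seed(seed + 1L, {
    trials <- NULL
    per_sf <- list()
    for (sf in unique(schedule$sf_cpd)) {
      block <- schedule[schedule$sf_cpd == sf, ]
      quest <- quest_init(ladder = plan$ladder)
      for (i in seq_len(nrow(block))) {
        contrast <- quest_next_contrast(quest)
        stim <- stimulus_spec(sf_cpd = sf, contrast = contrast,
                              direction = block$direction[i],
                              velocity_dps = plan$velocity_dps,
                              duration_max_s = plan$timeout_s)
        obs <- observe_trial(observer, stim, seed = NULL, rate_hz = rate_hz)
        if (detector == "oracle") {
          decision <- if (obs$label == "okn") "seen" else "not_seen"
          dtime <- NA_real_
        } else if (detector == "live") {
          det <- run_live(obs$trace, stim, config)
          decision <- if (det$okn_present) "seen" else "not_seen"
          dtime <- det$decision_time_ms
        } else {
          det <- analyze_trial_offline(obs$trace, stim, config)
          decision <- if (det$okn_present) "seen" else "not_seen"
          dtime <- det$decision_time_ms
        }
        quest <- quest_update(quest, contrast, decision)
        trials <- rbind(trials, data.frame(
          sf_cpd = sf, trial = block$trial[i], contrast = contrast,
          direction = block$direction[i], label = obs$label,
          decision = decision, decision_time_ms = dtime))
      }
      tab_df <- trials[trials$sf_cpd == sf, ]
      tab_df$n <- 1L
      tab_df$seen <- as.integer(tab_df$decision == "seen")
      agg <- stats::aggregate(cbind(n, seen) ~ contrast, data = tab_df,
                              FUN = sum)
      tab <- outcome_table(agg$contrast, agg$n, agg$seen)
      fit <- suppressWarnings(fit_psychometric(tab, ladder = plan$ladder))
      per_sf[[as.character(sf)]] <- list(
        sf_cpd = sf, table = tab, fit = fit, quest = quest,
        ct = fit$params$ct, cs = fit$params$cs)
    }
    cs_table <- data.frame(
      sf_cpd = vapply(per_sf, `[[`, numeric(1), "sf_cpd"),
      cs = vapply(per_sf, `[[`, numeric(1), "cs"))
    # a CSF needs at least 4 frequencies; smaller runs return fits only
    csf <- if (nrow(cs_table) >= 4L) fit_csf(cs_table) else NULL
    structure(list(trials = trials, per_sf = per_sf, cs_table = cs_table,
                   csf = csf, plan = plan, observer = observer, seed = seed,
                   detector = detector),
              class = "okn_experiment")
  })
}

#' @export
print.okn_experiment <- function(x, ...) {
  cat(sprintf(
    "<okn_experiment> %d trials over %d spatial frequencies (detector: %s, seed %d)\n",
    nrow(x$trials), length(x$per_sf), x$detector, x$seed))
  tab <- summary(x)$per_sf
  print(tab, digits = 3, row.names = FALSE)
  if (!is.null(x$csf)) {
    cat("CSF: ")
    print(x$csf$params)
  }
  invisible(x)
}

#' @export
summary.okn_experiment <- function(object, ...) {
  truth <- object$observer$true_params
  tab <- do.call(rbind, lapply(object$per_sf, function(b) {
    data.frame(sf_cpd = b$sf_cpd, ct = b$ct, cs = b$cs,
               m_hat = b$fit$params$m, w_hat = b$fit$params$w,
               converged = b$fit$converged)
  }))
  tab$m_true <- truth$m[match(tab$sf_cpd, truth$sf_cpd)]
  tab$m_error <- tab$m_hat - tab$m_true
  rownames(tab) <- NULL
  structure(list(per_sf = tab,
                 csf = if (!is.null(object$csf)) object$csf$params,
                 detector = object$detector, n_trials = nrow(object$trials)),
            class = "summary.okn_experiment")
}

#' @export
print.summary.okn_experiment <- function(x, ...) {
  cat(sprintf("Closed-loop OKN contrast-sensitivity run (%s detector, %d trials)\n",
              x$detector, x$n_trials))
  print(x$per_sf, digits = 3, row.names = FALSE)
  if (!is.null(x$csf)) {
    cat("Fitted CSF: ")
    print(x$csf)
  }
  invisible(x)
}

#' @export
plot.okn_experiment <- function(x, ...) {
  if (is.null(x$csf)) {
    stop_okncs("no CSF fit to plot (fewer than 4 spatial frequencies)",
               "okncs_insufficient_data")
  }
  plot(x$csf, main = "Recovered contrast-sensitivity function", ...)
  truth <- x$observer$true_params
  graphics::points(truth$sf_cpd, exp(-truth$m), pch = 4)
  graphics::legend("bottomleft", pch = c(1, 4),
                   legend = c("recovered", "ground truth"), bty = "n")
  invisible(x)
}

#' Score detectors against a labelled synthetic corpus
#'
#' Runs the live and/or offline detectors over a corpus from
#' [synth_corpus()] and scores decisions against the generator's
#' ground-truth labels.
#'
#' @param corpus a list as returned by [synth_corpus()].
#' @param stimulus the [stimulus_spec()] used for the positive class.
#' @param config_live,config_offline detector configurations.
#' @param mode `"both"`, `"live"` or `"offline"`.
#' @return list with the per-trace `decisions` data frame and a `metrics`
#'   list holding sensitivity, specificity per detector and live/offline
#'   concordance (fractions in [0, 1]).
#' @export
evaluate_detectors <- function(corpus, stimulus,
                               config_live = detector_config("live"),
                               config_offline = detector_config("offline"),
                               mode = c("both", "live", "offline")) {
  mode <- match.arg(mode)
  res <- lapply(seq_along(corpus$traces), function(i) {
    tr <- corpus$traces[[i]]
    stim <- stimulus
    stim$direction <- corpus$manifest$direction[i]
    out <- list(id = i, label = corpus$manifest$label[i],
                live = NA, offline = NA)
    if (mode != "offline") {
      out$live <- run_live(tr, stim, config_live)$okn_present
    }
    if (mode != "live") {
      out$offline <- analyze_trial_offline(tr, stim, config_offline)$okn_present
    }
    out
  })
  dec <- do.call(rbind, lapply(res, as.data.frame))
  pos <- dec$label == "okn"
  metric <- function(col) {
    if (all(is.na(dec[[col]]))) return(NULL)
    list(sensitivity = mean(dec[[col]][pos]),
         specificity = mean(!dec[[col]][!pos]))
  }
  metrics <- list(live = metric("live"), offline = metric("offline"))
  if (mode == "both") {
    metrics$concordance <- mean(dec$live == dec$offline)
  }
  list(decisions = dec, metrics = metrics)
}
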