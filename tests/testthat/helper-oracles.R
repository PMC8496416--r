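# Independent brute-force oracles and small fixture builders. Each oracle
# re-implements the rule it checks from its plain-language definition,
# deliberately avoiding the package's code paths.

# --- fixture builders -------------------------------------------------------

# trace with identical given x positions in both eyes, no blinks
make_trace <- function(x, rate_hz = 1000, x_right = x) {
  n <- length(x)
  gaze_trace(data.frame(
    t = seq(0, by = 1000 / rate_hz, length.out = n),
    x_left = x, y_left = 0, pupil_left = 1000,
    x_right = x_right, y_right = 0, pupil_right = 1000), rate_hz = rate_hz)
}

# velocity_trace straight from numbers (bypasses the kernel)
make_velocity <- function(v_left, v_right = v_left, rate_hz = 1000) {
  out <- data.frame(t = seq(0, by = 1000 / rate_hz,
                            length.out = length(v_left)),
                    v_left = v_left, v_right = v_right)
  class(out) <- c("velocity_trace", "data.frame")
  attr(out, "rate_hz") <- rate_hz
  out
}

# mirror a trace (and its events) through x = 0
mirror_trace <- function(trace) {
  trace$samples$x_left <- -trace$samples$x_left
  trace$samples$x_right <- -trace$samples$x_right
  trace
}

# --- oracle: median-based noise sigma --------------------------------------

oracle_sigma <- function(v) {
  v <- v[is.finite(v)]
  sqrt(max(0, median(v^2) - median(v)^2))
}

# --- oracle: saccade detection ---------------------------------------------

# exhaustive enumeration: all maximal supra-threshold runs per eye, keep a
# monocular run only if it shares >= 1 sample with some run of the other
# eye, report the union of each connected overlap component, drop short
# events, then merge events separated by less than min_separation_ms
oracle_saccades <- function(v_left, v_right, eta_left, eta_right, dt_ms,
                            min_duration_ms, min_separation_ms,
                            binocular_required) {
  runs_of <- function(v, eta) {
    supra <- !is.na(v) & abs(v) > eta
    out <- NULL
    i <- 1L
    while (i <= length(supra)) {
      if (supra[i]) {
        j <- i
        while (j < length(supra) && supra[j + 1L]) j <- j + 1L
        out <- rbind(out, c(i, j))
        i <- j + 1L
      } else i <- i + 1L
    }
    out
  }
  rl <- runs_of(v_left, eta_left)
  rr <- runs_of(v_right, eta_right)
  overlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]
  if (binocular_required) {
    if (is.null(rl) || is.null(rr)) return(NULL)
    all_runs <- rbind(rl, rr)
    eye <- c(rep("L", nrow(rl)), rep("R", nrow(rr)))
    keep <- vapply(seq_len(nrow(all_runs)), function(i) {
      other <- all_runs[eye != eye[i], , drop = FALSE]
      any(vapply(seq_len(nrow(other)),
                 function(j) overlap(all_runs[i, ], other[j, ]), logical(1)))
    }, logical(1))
    runs <- all_runs[keep, , drop = FALSE]
  } else {
    runs <- rbind(rl, rr)
  }
  if (is.null(runs) || nrow(runs) == 0L) return(NULL)
  # connected components under interval overlap -> union intervals
  runs <- runs[order(runs[, 1L]), , drop = FALSE]
  events <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    k <- nrow(events)
    if (runs[i, 1L] <= events[k, 2L]) {
      events[k, 2L] <- max(events[k, 2L], runs[i, 2L])
    } else events <- rbind(events, runs[i, , drop = FALSE])
  }
  dur <- (events[, 2L] - events[, 1L] + 1L) * dt_ms
  events <- events[dur >= min_duration_ms, , drop = FALSE]
  if (nrow(events) == 0L) return(NULL)
  if (min_separation_ms > 0 && nrow(events) > 1L) {
    merged <- events[1L, , drop = FALSE]
    for (i in seq_len(nrow(events))[-1L]) {
      k <- nrow(merged)
      if ((events[i, 1L] - merged[k, 2L] - 1L) * dt_ms < min_separation_ms) {
        merged[k, 2L] <- events[i, 2L]
      } else merged <- rbind(merged, events[i, , drop = FALSE])
    }
    events <- merged
  }
  unname(events)
}

# --- oracle: blink-mask dilation -------------------------------------------

# set dilation: a sample is invalid iff some track-lost sample lies within
# buffer_ms of it
oracle_blink_mask <- function(t, lost, buffer_ms) {
  vapply(seq_along(t), function(i) {
    !any(lost & abs(t - t[i]) <= buffer_ms)
  }, logical(1))
}

# --- oracles: QUEST+ --------------------------------------------------------

oracle_psi <- function(x, m, w) {
  cc <- log(-log(0.05)) - log(-log(0.95))
  1 - exp(log(0.5) * exp(cc * (log(x) - m) / w))
}

# posterior from scratch: product of per-trial likelihoods over the dense
# grid, renormalized once at the end
oracle_quest_posterior <- function(ladder, slopes, history) {
  cc <- log(-log(0.05)) - log(-log(0.95))
  post <- matrix(1, length(ladder), length(slopes))
  for (r in seq_len(nrow(history))) {
    for (j in seq_along(ladder)) {
      for (k in seq_along(slopes)) {
        p <- oracle_psi(history$contrast[r], log(ladder[j]), cc / slopes[k])
        post[j, k] <- post[j, k] *
          (if (history$outcome[r] == "seen") p else 1 - p)
      }
    }
  }
  post / sum(post)
}

# expected posterior entropy of every candidate level, by full enumeration
oracle_expected_entropies <- function(ladder, slopes, posterior) {
  cc <- log(-log(0.05)) - log(-log(0.95))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  vapply(seq_along(ladder), function(i) {
    p_seen <- outer(seq_along(ladder), seq_along(slopes),
                    Vectorize(function(j, k)
                      oracle_psi(ladder[i], log(ladder[j]), cc / slopes[k])))
    p1 <- sum(posterior * p_seen)
    post1 <- posterior * p_seen
    post0 <- posterior * (1 - p_seen)
    e <- 0
    if (p1 > 0) e <- e + p1 * H(post1 / sum(post1))
    if (p1 < 1) e <- e + (1 - p1) * H(post0 / sum(post0))
    e
  }, numeric(1))
}

# --- oracle: psychometric MLE by dense grid search -------------------------

oracle_psych_loglik <- function(table, m, w) {
  p <- pmin(pmax(oracle_psi(table$contrast, m, w), 1e-12), 1 - 1e-12)
  sum(table$n_seen * log(p) +
        (table$n_presented - table$n_seen) * log(1 - p))
}

# dense grid search with one zoom stage around the coarse argmax; also
# reports the spread of near-optimal m values (the likelihood can form a
# ridge trading m against w, where the maximizer is not unique)
oracle_psych_mle <- function(table, m_range, n_m = 121L, n_w = 61L) {
  scan <- function(ms, ws) {
    best <- c(NA, NA)
    best_ll <- -Inf
    near_m <- numeric(0)
    ll_mat <- matrix(NA_real_, length(ms), length(ws))
    for (i in seq_along(ms)) {
      for (j in seq_along(ws)) {
        ll_mat[i, j] <- oracle_psych_loglik(table, ms[i], ws[j])
        if (ll_mat[i, j] > best_ll) {
          best_ll <- ll_mat[i, j]
          best <- c(ms[i], ws[j])
        }
      }
    }
    near <- which(ll_mat >= best_ll - 0.05, arr.ind = TRUE)
    list(m = best[1L], w = best[2L], logLik = best_ll,
         m_near_range = range(ms[near[, 1L]]))
  }
  ms <- seq(m_range[1L], m_range[2L], length.out = n_m)
  ws <- exp(seq(log(0.05), log(10), length.out = n_w))
  coarse <- scan(ms, ws)
  dm <- diff(ms)[1L]
  dlogw <- diff(log(ws))[1L]
  fine <- scan(seq(coarse$m - 2 * dm, coarse$m + 2 * dm, length.out = 41L),
               exp(seq(log(coarse$w) - 2 * dlogw, log(coarse$w) + 2 * dlogw,
                       length.out = 41L)))
  list(m = fine$m, w = fine$w, logLik = fine$logLik,
       dm = dm, dlogw = dlogw, m_near_range = coarse$m_near_range)
}
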