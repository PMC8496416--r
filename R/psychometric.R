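# The cumulative-Weibull psychometric model: evaluation, maximum-likelihood
# fitting of (m, w) from trial-outcome tables, and conversion to contrast
# threshold and sensitivity.
#
# Parametrization: Psi(x; m, w, gamma, lambda) =
#   gamma + (1 - lambda - gamma) * (1 - exp(log(0.5) * exp(c*(log(x)-m)/w)))
# with c = log(-log 0.05) - log(-log 0.95). m is the natural-log threshold
# (Psi = 0.5 at x = e^m when gamma = lambda = 0) and w the width of the
# 0.05-0.95 zone in natural-log stimulus units. All logs are natural; that
# is what makes the quantile identity Psi^{-1}(0.95) - Psi^{-1}(0.05) = w
# exact.

#' The Weibull width constant c
#'
#' `c = log(-log(0.05)) - log(-log(0.95))`, the constant tying the width
#' `w` (the log-stimulus span between the 5% and 95% points) to the slope
#' `s = c / w`.
#'
#' @return the constant, about 4.067.
#' @export
weibull_c <- function() log(-log(0.05)) - log(-log(0.95))

#' Psychometric function parameters
#'
#' @param m natural-log contrast threshold.
#' @param w width in natural-log contrast units (`> 0`).
#' @param gamma_guess lower asymptote (guess rate), default 0.
#' @param lambda_lapse upper-asymptote complement (lapse rate), default 0.
#' @return object of class `psychometric_params` with derived fields
#'   `slope` (`= c/w`), `ct` (contrast threshold `e^m`) and `cs`
#'   (contrast sensitivity `1/ct`).
#' @export
psychometric_params <- function(m, w, gamma_guess = 0, lambda_lapse = 0) {
  if (!(w > 0)) stop_okncs("width w must be positive", "okncs_domain_error")
  if (gamma_guess < 0 || lambda_lapse < 0 || gamma_guess + lambda_lapse >= 1) {
    stop_okncs("asymptotes must satisfy 0 <= gamma + lambda < 1",
               "okncs_domain_error")
  }
  structure(list(m = m, w = w, gamma_guess = gamma_guess,
                 lambda_lapse = lambda_lapse, slope = weibull_c() / w,
                 ct = exp(m), cs = exp(-m)),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "<psychometric_params> m=%.4f (CT=%.4g, CS=%.4g), w=%.4f (slope=%.3f), guess=%g, lapse=%g\n",
    x$m, x$ct, x$cs, x$w, x$slope, x$gamma_guess, x$lambda_lapse))
  invisible(x)
}

#' Cumulative Weibull psychometric function
#'
#' Probability of a positive response (here: an OKN response) at stimulus
#' contrast `x`.
#'
#' @param x stimulus level (contrast fraction), `> 0`.
#' @param params a [psychometric_params()], or a list with `m`, `w` and
#'   optionally `gamma_guess`, `lambda_lapse`.
#' @return probability in `[gamma, 1 - lambda]`, strictly increasing in x.
#' @examples
#' p <- psychometric_params(m = log(0.05), w = 1)
#' weibull_psi(0.05, p)  # 0.5 at the threshold
#' @export
weibull_psi <- function(x, params) {
  if (any(x <= 0)) stop_okncs("stimulus level must be positive",
                              "okncs_domain_error")
  g <- params$gamma_guess %||% 0
  l <- params$lambda_lapse %||% 0
  g + (1 - l - g) * (1 - exp(log(0.5) * exp(weibull_c() * (log(x) - params$m) /
                                              params$w)))
}

#' Quantile of the psychometric function (log-stimulus units)
#'
#' Inverse of [weibull_psi()] on the core CDF (asymptotes removed):
#' `u_p = m + (w/c) * log(log(1 - p) / log(0.5))`.
#'
#' @param p probability in (0, 1).
#' @param params a [psychometric_params()].
#' @return natural-log stimulus level at which the core CDF reaches `p`.
#' @export
weibull_quantile <- function(p, params) {
  stopifnot(all(p > 0 & p < 1))
  params$m + (params$w / weibull_c()) * log(log(1 - p) / log(0.5))
}

#' Convert between psychometric width and slope
#'
#' `s = c / w` and `w = c / s`; the conversion is an involution.
#'
#' @param value positive width or slope.
#' @return the converted value.
#' @export
width_slope_convert <- function(value) {
  if (any(value <= 0)) stop_okncs("width/slope must be positive",
                                  "okncs_domain_error")
  weibull_c() / value
}

#' Contrast threshold and sensitivity of fitted parameters
#'
#' @param params a [psychometric_params()] or `psychfit`.
#' @return named vector `c(ct, cs)` with `ct = e^m`, `cs = 1/ct`.
#' @export
threshold_to_cs <- function(params) {
  m <- if (inherits(params, "psychfit")) params$params$m else params$m
  c(ct = exp(m), cs = exp(-m))
}

#' Outcome table
#'
#' Per-contrast trial counts for psychometric fitting.
#'
#' @param contrast contrast fractions in (0, 1].
#' @param n_presented presentations per level.
#' @param n_seen positive outcomes per level.
#' @return data frame of class `outcome_table`.
#' @export
outcome_table <- function(contrast, n_presented, n_seen) {
  stopifnot(length(contrast) == length(n_presented),
            length(contrast) == length(n_seen))
  if (any(contrast <= 0 | contrast > 1)) {
    stop_okncs("contrast must be in (0, 1]", "okncs_domain_error")
  }
  if (any(n_seen < 0 | n_seen > n_presented)) {
    stop_okncs("need 0 <= n_seen <= n_presented", "okncs_data_error")
  }
  out <- data.frame(contrast = contrast, n_presented = n_presented,
                    n_seen = n_seen)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Read / write outcome tables as delimited text
#'
#' Header `contrast,n_presented,n_seen`, one contrast level per row.
#'
#' @param path file path.
#' @return an [outcome_table()].
#' @export
read_outcome_table <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("contrast", "n_presented", "n_seen")
  if (!all(need %in% names(raw))) {
    stop_okncs(sprintf("outcome table %s lacks column(s): %s", path,
                       paste(setdiff(need, names(raw)), collapse = ", ")),
               "okncs_format_error")
  }
  outcome_table(raw$contrast, raw$n_presented, raw$n_seen)
}

#' @rdname read_outcome_table
#' @param table an [outcome_table()].
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# negative log-likelihood of (m, w) for an outcome table (product-binomial)
psych_nll <- function(m, w, table, gamma_guess = 0, lambda_lapse = 0) {
  p <- gamma_guess + (1 - lambda_lapse - gamma_guess) *
    (1 - exp(log(0.5) * exp(weibull_c() * (log(table$contrast) - m) / w)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(table$n_seen * log(p) + (table$n_presented - table$n_seen) * log(1 - p))
}

#' Fit the cumulative Weibull psychometric function by maximum likelihood
#'
#' Maximizes the product-binomial likelihood of `(m, w)` over an outcome
#' table with the asymptotes fixed (both zero by default), by a coarse
#' grid search followed by local refinement. The threshold `m` is bounded
#' to the span of the contrast ladder plus one ladder step on each side.
#'
#' @param table an [outcome_table()] (or data frame with columns
#'   `contrast`, `n_presented`, `n_seen`).
#' @param gamma_guess,lambda_lapse fixed asymptotes (default 0).
#' @param ladder contrast ladder defining the admissible threshold span
#'   (default [contrast_ladder()]).
#' @return An object of class `psychfit`: list with `params`
#'   (a [psychometric_params()]), `logLik`, `converged`, `table`, and the
#'   derived threshold/sensitivity. Standard methods `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `plot` and `simulate` are provided.
#' @details A table in which every trial was seen (or none was) does not
#'   identify an interior threshold; the fit then returns the boundary
#'   estimate with `converged = FALSE` and a warning.
#' @export
fit_psychometric <- function(table, gamma_guess = 0, lambda_lapse = 0,
                             ladder = contrast_ladder()) {
  if (!inherits(table, "outcome_table")) {
    table <- outcome_table(table$contrast, table$n_presented, table$n_seen)
  }
  agg <- stats::aggregate(cbind(n_presented, n_seen) ~ contrast,
                          data = as.data.frame(table), FUN = sum)
  step <- mean(diff(log(ladder)))
  m_lo <- log(min(ladder)) - step
  m_hi <- log(max(ladder)) + step
  total_seen <- sum(agg$n_seen)
  total <- sum(agg$n_presented)
  degenerate <- total_seen == 0L || total_seen == total
  # coarse grid, then bounded refinement from the best few cells; the
  # refined value is never allowed below its start (flat ridges in w can
  # stall the quasi-Newton step)
  m_grid <- seq(m_lo, m_hi, length.out = 41L)
  w_grid <- exp(seq(log(0.05), log(10), length.out = 25L))
  grid <- expand.grid(m = m_grid, w = w_grid)
  nll <- mapply(psych_nll, grid$m, grid$w,
                MoreArgs = list(table = agg, gamma_guess = gamma_guess,
                                lambda_lapse = lambda_lapse))
  objective <- function(par) psych_nll(par[1L], exp(par[2L]), agg,
                                       gamma_guess, lambda_lapse)
  best <- list(par = NULL, value = Inf, convergence = 1L)
  for (i in order(nll)[1:3]) {
    start <- c(grid$m[i], log(grid$w[i]))
    opt <- stats::optim(start, objective, method = "L-BFGS-B",
                        lower = c(m_lo, log(1e-3)),
                        upper = c(m_hi, log(20)))
    if (opt$value > nll[i]) {
      opt <- list(par = start, value = nll[i], convergence = 0L)
    }
    if (opt$value < best$value) best <- opt
  }
  m_hat <- best$par[1L]
  w_hat <- exp(best$par[2L])
  converged <- best$convergence == 0L && !degenerate
  if (degenerate) {
    m_hat <- if (total_seen == 0L) m_hi else m_lo
    warning(paste("outcome table has no mixed outcomes;",
                  "returning the boundary threshold estimate"))
  }
  params <- psychometric_params(m_hat, w_hat, gamma_guess, lambda_lapse)
  structure(list(params = params, logLik = -psych_nll(m_hat, w_hat, agg,
                                                      gamma_guess,
                                                      lambda_lapse),
                 converged = converged, table = agg,
                 bounds = c(m_lo = m_lo, m_hi = m_hi)),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Cumulative Weibull psychometric fit (maximum likelihood)\n")
  print(x$params)
  cat(sprintf("  logLik %.3f, %sconverged; %d levels, %d trials\n",
              x$logLik, if (x$converged) "" else "NOT ",
              nrow(x$table), sum(x$table$n_presented)))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  p <- object$params
  c(m = p$m, w = p$w, slope = p$slope, ct = p$ct, cs = p$cs)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = 2L, class = "logLik")
}

#' @export
summary.psychfit <- function(object, ...) {
  p <- object$params
  obs <- object$table
  obs$p_obs <- obs$n_seen / obs$n_presented
  obs$p_fit <- weibull_psi(obs$contrast, p)
  structure(list(fit = object, table = obs), class = "summary.psychfit")
}

#' @export
print.summary.psychfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  CT = %.4g (%.3g%% contrast), CS = %.4g\n",
              x$fit$params$ct, 100 * x$fit$params$ct, x$fit$params$cs))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$table$contrast
  else if (is.data.frame(newdata)) newdata$contrast else newdata
  weibull_psi(x, object$params)
}

#' @export
plot.psychfit <- function(x, n_curve = 200L, ...) {
  obs <- x$table
  xs <- exp(seq(log(min(obs$contrast)) - 0.5, log(max(obs$contrast)) + 0.5,
                length.out = n_curve))
  plot(obs$contrast, obs$n_seen / obs$n_presented, log = "x",
       xlab = "Michelson contrast", ylab = "P(OKN seen)", ylim = c(0, 1),
       cex = sqrt(obs$n_presented), ...)
  graphics::lines(xs, weibull_psi(xs, x$params))
  graphics::abline(v = x$params$ct, lty = 2)
  invisible(x)
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      tb <- object$table
      tb$n_seen <- stats::rbinom(nrow(tb), tb$n_presented,
                                 weibull_psi(tb$contrast, object$params))
      outcome_table(tb$contrast, tb$n_presented, tb$n_seen)
    })
  })
}
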