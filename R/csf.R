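# Log-parabola contrast-sensitivity function across spatial frequencies:
#   log10 CS(SF) = log10(gamma_max)
#                  - log10(2) * ((log10 SF - log10 SF_max) / (beta / 2))^2
# gamma_max is the peak sensitivity, SF_max the peak spatial frequency
# (cpd) and beta the full bandwidth in log10-cpd units: at
# |log10 SF - log10 SF_max| = beta/2 the sensitivity is halved. Fitting
# and the coefficient of determination are computed in log10-CS space,
# where the model is a plain quadratic in log10 SF.

#' CSF parameters
#'
#' @param gamma_max peak contrast sensitivity (> 0).
#' @param sf_max peak spatial frequency in cpd (> 0).
#' @param beta bandwidth in log10-cpd units (> 0).
#' @param r2 optional coefficient of determination of a fit.
#' @return object of class `csf_params`.
#' @export
csf_params <- function(gamma_max, sf_max, beta, r2 = NA_real_) {
  if (!(gamma_max > 0 && sf_max > 0 && beta > 0)) {
    stop_okncs("CSF parameters must be positive", "okncs_domain_error")
  }
  if (!is.na(r2) && r2 > 1) {
    stop_okncs("r2 cannot exceed 1", "okncs_domain_error")
  }
  structure(list(gamma_max = unname(gamma_max), sf_max = unname(sf_max),
                 beta = unname(beta), r2 = unname(r2)),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "<csf_params> gamma_max=%.4g, SF_max=%.3g cpd, beta=%.3g log10-cpd%s\n",
    x$gamma_max, x$sf_max, x$beta,
    if (is.na(x$r2)) "" else sprintf(", R^2=%.4f", x$r2)))
  invisible(x)
}

#' Log-parabola CSF model
#'
#' @param sf spatial frequency in cpd, `> 0`.
#' @param params a [csf_params()] (or list with `gamma_max`, `sf_max`,
#'   `beta`).
#' @return `log10` contrast sensitivity at `sf`; maximal
#'   (`log10(gamma_max)`) at `sf = sf_max` and symmetric in `log10 sf`
#'   about `log10 sf_max`.
#' @export
logparabola <- function(sf, params) {
  if (any(sf <= 0)) stop_okncs("spatial frequency must be positive",
                               "okncs_domain_error")
  log10(params$gamma_max) -
    log10(2) * ((log10(sf) - log10(params$sf_max)) / (params$beta / 2))^2
}

csf_ss <- function(par, l_sf, y) {
  # par = (log10 gamma_max, log10 sf_max, log beta)
  beta <- exp(par[3L])
  pred <- par[1L] - log10(2) * ((l_sf - par[2L]) / (beta / 2))^2
  sum((y - pred)^2)
}

#' Fit a log-parabola contrast-sensitivity function
#'
#' Least squares in log10-sensitivity space. The closed-form quadratic
#' regression of `log10 CS` on `log10 SF` provides the start (falling
#' back to the empirical peak when the quadratic opens upward), followed
#' by bounded local refinement with `sf_max` constrained to
#' `[min(sf)/2, 2*max(sf)]`.
#'
#' @param points data frame with columns `sf_cpd` and `cs` (contrast
#'   sensitivity, linear units), at least 4 rows; ideally with points on
#'   both sides of the empirical peak.
#' @return An object of class `csffit`: list with `params`
#'   (a [csf_params()] including `r2`), `points`, `fitted` and
#'   `residuals` (log10 units). Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @details `r2 = 1 - SS_res/SS_tot` in log10 space; for degenerate
#'   constant-sensitivity data (`SS_tot = 0`) `r2` is reported as 0 with
#'   a warning.
#' @export
fit_csf <- function(points) {
  if (!all(c("sf_cpd", "cs") %in% names(points))) {
    stop_okncs("points need columns sf_cpd and cs", "okncs_format_error")
  }
  if (nrow(points) < 4L) {
    stop_okncs("CSF fitting needs at least 4 points",
               "okncs_insufficient_data")
  }
  if (any(points$sf_cpd <= 0 | points$cs <= 0)) {
    stop_okncs("sf_cpd and cs must be positive", "okncs_domain_error")
  }
  l_sf <- log10(points$sf_cpd)
  y <- log10(points$cs)
  lo_sf <- log10(min(points$sf_cpd) / 2)
  hi_sf <- log10(max(points$sf_cpd) * 2)
  # closed-form quadratic start
  qfit <- stats::lm(y ~ l_sf + I(l_sf^2))
  q <- stats::coef(qfit)
  if (is.finite(q[3L]) && q[3L] < 0) {
    l0 <- -q[2L] / (2 * q[3L])
    beta0 <- 2 * sqrt(log10(2) / -q[3L])
    g0 <- q[1L] - q[2L]^2 / (4 * q[3L])
  } else {
    l0 <- l_sf[which.max(y)]
    beta0 <- 2
    g0 <- max(y)
  }
  l0 <- min(max(l0, lo_sf), hi_sf)
  start <- unname(c(g0, l0, log(beta0)))
  opt <- stats::optim(start, csf_ss, l_sf = l_sf, y = y,
                      method = "L-BFGS-B",
                      lower = c(-2, lo_sf, log(0.05)),
                      upper = c(6, hi_sf, log(50)))
  par <- opt$par
  fitted <- par[1L] - log10(2) * ((l_sf - par[2L]) / (exp(par[3L]) / 2))^2
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) {
    warning("constant sensitivities: flat data, R^2 reported as 0")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  params <- csf_params(10^par[1L], 10^par[2L], exp(par[3L]), r2 = r2)
  structure(list(params = params, points = points, fitted = fitted,
                 residuals = res, convergence = opt$convergence),
            class = "csffit")
}

#' @export
print.csffit <- function(x, ...) {
  cat("Log-parabola CSF fit (least squares in log10 space)\n")
  print(x$params)
  cat(sprintf("  %d points, residual SD %.4f log10 units\n",
              nrow(x$points), stats::sd(x$residuals)))
  invisible(x)
}

#' @export
coef.csffit <- function(object, ...) {
  p <- object$params
  c(gamma_max = p$gamma_max, sf_max = p$sf_max, beta = p$beta, r2 = p$r2)
}

#' @export
summary.csffit <- function(object, ...) {
  tab <- object$points
  tab$log10_cs <- log10(tab$cs)
  tab$fitted <- object$fitted
  tab$residual <- object$residuals
  structure(list(fit = object, table = tab), class = "summary.csffit")
}

#' @export
print.summary.csffit <- function(x, ...) {
  print(x$fit)
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
predict.csffit <- function(object, newdata = NULL,
                           type = c("log10", "linear"), ...) {
  type <- match.arg(type)
  sf <- if (is.null(newdata)) object$points$sf_cpd
  else if (is.data.frame(newdata)) newdata$sf_cpd else newdata
  val <- logparabola(sf, object$params)
  if (type == "linear") 10^val else val
}

#' @export
residuals.csffit <- function(object, ...) object$residuals

#' @export
plot.csffit <- function(x, n_curve = 200L, ...) {
  pts <- x$points
  sfs <- 10^seq(log10(min(pts$sf_cpd)) - 0.1, log10(max(pts$sf_cpd)) + 0.1,
                length.out = n_curve)
  plot(pts$sf_cpd, pts$cs, log = "xy",
       xlab = "Spatial frequency (cpd)", ylab = "Contrast sensitivity", ...)
  graphics::lines(sfs, 10^logparabola(sfs, x$params))
  invisible(x)
}

#' Densely sampled CSF curve table
#'
#' @param params a [csf_params()] or `csffit`.
#' @param sf_range range of spatial frequencies (cpd).
#' @param n number of samples.
#' @return data frame `sf_cpd`, `log10_cs`, `cs`.
#' @export
csf_curve <- function(params, sf_range = c(0.5, 8), n = 100L) {
  if (inherits(params, "csffit")) params <- params$params
  sf <- 10^seq(log10(sf_range[1L]), log10(sf_range[2L]), length.out = n)
  l <- logparabola(sf, params)
  data.frame(sf_cpd = sf, log10_cs = l, cs = 10^l)
}
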