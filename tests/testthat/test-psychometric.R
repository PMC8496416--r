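test_that("the Weibull evaluates to 0.5 at threshold with zero asymptotes", {
  for (m in c(log(0.05), log(0.3), -7)) {
    for (w in c(0.3, 1, 4)) {
      p <- psychometric_params(m, w)
      expect_equal(weibull_psi(exp(m), p), 0.5)
    }
  }
  expect_error(weibull_psi(-0.1, psychometric_params(0, 1)),
               class = "okncs_domain_error")
  expect_error(psychometric_params(0, -1), class = "okncs_domain_error")
})

test_that("the 0.05-0.95 quantile separation equals the width w", {
  set.seed(12)
  for (i in 1:100) {
    p <- psychometric_params(m = runif(1, -8, 0), w = runif(1, 0.1, 6))
    u95 <- weibull_quantile(0.95, p)
    u05 <- weibull_quantile(0.05, p)
    expect_equal(u95 - u05, p$w, tolerance = 1e-9)
    # quantiles invert the function
    expect_equal(weibull_psi(exp(u95), p), 0.95, tolerance = 1e-9)
    expect_equal(weibull_psi(exp(u05), p), 0.05, tolerance = 1e-9)
  }
})

test_that("asymptotes and monotonicity behave as a CDF", {
  p <- psychometric_params(log(0.05), 1, gamma_guess = 0.02,
                           lambda_lapse = 0.03)
  expect_equal(weibull_psi(1e-12, p), 0.02, tolerance = 1e-6)
  expect_equal(weibull_psi(1e6, p), 0.97, tolerance = 1e-6)

  set.seed(13)
  for (i in 1:20) {
    pp <- psychometric_params(runif(1, -7, -1), runif(1, 0.2, 5))
    xs <- sort(exp(runif(50, -9, 0)))
    vals <- weibull_psi(xs, pp)
    expect_true(all(diff(vals) >= 0))
    # increasing m shifts the curve right: probability falls at fixed x
    pp2 <- psychometric_params(pp$m + 0.5, pp$w)
    expect_true(all(weibull_psi(xs, pp2) <= vals + 1e-12))
  }
})

test_that("width/slope conversion is an involution through c", {
  cc <- weibull_c()
  expect_equal(cc, log(-log(0.05)) - log(-log(0.95)))
  expect_equal(width_slope_convert(cc), 1)
  expect_equal(width_slope_convert(1), cc)
  for (v in c(0.2, 1, 3.7)) {
    expect_equal(width_slope_convert(width_slope_convert(v)), v)
  }
  expect_error(width_slope_convert(0), class = "okncs_domain_error")
})

test_that("threshold and sensitivity derive from m", {
  expect_equal(threshold_to_cs(psychometric_params(0, 1)),
               c(ct = 1, cs = 1))
  expect_equal(threshold_to_cs(psychometric_params(log(0.01), 1)),
               c(ct = 0.01, cs = 100))
  ms <- seq(-6, -1, by = 0.5)
  cs <- vapply(ms, function(m)
    threshold_to_cs(psychometric_params(m, 1))[["cs"]], numeric(1))
  expect_true(all(diff(cs) < 0))  # CS strictly decreasing in m
})

test_that("outcome tables validate their counts", {
  expect_s3_class(outcome_table(c(0.1, 0.2), c(5, 5), c(1, 4)),
                  "outcome_table")
  expect_error(outcome_table(c(0.1), 5, 6), class = "okncs_data_error")
  expect_error(outcome_table(c(1.2), 5, 2), class = "okncs_domain_error")
  f <- tempfile(fileext = ".csv")
  tb <- outcome_table(c(0.05, 0.1, 0.2), c(10, 12, 9), c(2, 6, 9))
  write_outcome_table(tb, f)
  expect_equal(as.data.frame(read_outcome_table(f)), as.data.frame(tb))
})

test_that("MLE lands at the step of noiseless separable data", {
  ladder <- contrast_ladder()
  x0 <- ladder[20]
  tb <- outcome_table(ladder[15:25], rep(20, 11),
                      ifelse(ladder[15:25] > x0, 20, 0))
  fit <- fit_psychometric(tb)
  step <- median(diff(log(ladder)))
  expect_lt(abs(fit$params$m - log(x0)), 1.5 * step)
})

test_that("MLE matches the dense-grid oracle on random synthetic tables", {
  set.seed(21)
  ladder <- contrast_ladder()
  step <- median(diff(log(ladder)))
  for (i in 1:50) {
    m_true <- runif(1, log(ladder[8]), log(ladder[32]))
    w_true <- runif(1, 0.5, 3)
    levels <- sort(sample(ladder, sample(6:12, 1)))
    n <- sample(c(8, 16, 32), 1)
    p <- weibull_psi(levels, psychometric_params(m_true, w_true))
    tb <- outcome_table(levels, rep(n, length(levels)),
                        rbinom(length(levels), n, p))
    if (sum(tb$n_seen) == 0 || sum(tb$n_seen) == sum(tb$n_presented)) next
    fit <- fit_psychometric(tb)
    want <- oracle_psych_mle(tb, range(log(ladder)) + c(-step, step))
    # the reported likelihood is honest (independent recomputation) ...
    expect_equal(oracle_psych_loglik(tb, fit$params$m, fit$params$w),
                 fit$logLik, tolerance = 1e-8)
    # ... the optimizer reaches the (zoomed) dense grid's optimum height
    expect_gte(fit$logLik, want$logLik - 1e-4)
    expect_lt(abs(fit$logLik - want$logLik), 0.05)
    # ... and the threshold agrees within the oracle's own near-optimal
    # spread (the likelihood can form an m-w ridge where the argmax is
    # not unique) plus grid resolution
    spread <- diff(want$m_near_range)
    expect_lt(abs(fit$params$m - want$m), spread + 2 * want$dm)
  }
})

test_that("large-sample fits recover the generating parameters", {
  set.seed(31)
  ladder <- contrast_ladder()
  m_true <- log(ladder[18])
  w_true <- 1.4
  p <- weibull_psi(ladder, psychometric_params(m_true, w_true))
  tb <- outcome_table(ladder, rep(400, 39), rbinom(39, 400, p))
  fit <- fit_psychometric(tb)
  # asymptotic standard error from the dense-grid likelihood surface is
  # about w/(c*sqrt(n_eff)); 400 trials per level pins m very tightly
  expect_lt(abs(fit$params$m - m_true), 0.05)
  expect_lt(abs(fit$params$w - w_true), 0.15)
  expect_true(fit$converged)
})

test_that("duplicating every row leaves the MLE unchanged", {
  tb <- outcome_table(c(0.01, 0.02, 0.05, 0.1), c(10, 10, 10, 10),
                      c(1, 3, 7, 10))
  f1 <- fit_psychometric(tb)
  tb2 <- outcome_table(rep(tb$contrast, 2), rep(tb$n_presented, 2),
                       rep(tb$n_seen, 2))
  f2 <- fit_psychometric(tb2)
  expect_equal(f1$params$m, f2$params$m, tolerance = 1e-5)
  expect_equal(f1$params$w, f2$params$w, tolerance = 1e-4)
  expect_equal(f2$logLik, 2 * f1$logLik, tolerance = 1e-4)
})

test_that("all-seen and all-not-seen tables return flagged boundary fits", {
  ladder <- contrast_ladder()
  tb_all <- outcome_table(ladder[10:15], rep(8, 6), rep(8, 6))
  expect_warning(fit_all <- fit_psychometric(tb_all), "mixed")
  expect_false(fit_all$converged)
  expect_equal(fit_all$params$m, fit_all$bounds[["m_lo"]])

  tb_none <- outcome_table(ladder[10:15], rep(8, 6), rep(0, 6))
  expect_warning(fit_none <- fit_psychometric(tb_none), "mixed")
  expect_false(fit_none$converged)
  expect_equal(fit_none$params$m, fit_none$bounds[["m_hi"]])
})

test_that("psychfit methods expose coefficients, predictions, simulation", {
  set.seed(41)
  tb <- outcome_table(c(0.005, 0.01, 0.02, 0.05), rep(30, 4),
                      c(2, 8, 25, 30))
  fit <- fit_psychometric(tb)
  co <- coef(fit)
  expect_named(co, c("m", "w", "slope", "ct", "cs"))
  expect_equal(co[["ct"]], exp(co[["m"]]))
  expect_equal(co[["slope"]], weibull_c() / co[["w"]])
  expect_equal(predict(fit, co[["ct"]]), 0.5)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "outcome_table")
  expect_identical(simulate(fit, seed = 5)[[1]],
                   simulate(fit, seed = 5)[[1]])
})
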