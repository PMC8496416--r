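ladder <- contrast_ladder()
slopes <- seq(0.5, 5.5, by = 0.5)

test_that("initialization normalizes uniform, degenerate and custom priors", {
  q <- quest_init()
  expect_equal(dim(q$posterior), c(39L, 11L))
  expect_equal(as.vector(q$posterior), rep(1 / 429, 429))

  prior <- matrix(0, 39, 11)
  prior[17, 4] <- 5
  q2 <- quest_init(prior = prior)
  expect_equal(q2$posterior[17, 4], 1)
  expect_equal(sum(q2$posterior), 1)

  prior3 <- matrix(runif(429), 39, 11)
  q3 <- quest_init(prior = prior3)
  expect_equal(sum(q3$posterior), 1, tolerance = 1e-14)
  expect_equal(q3$posterior / q3$posterior[1, 1],
               prior3 / prior3[1, 1])

  expect_error(quest_init(ladder = c(0.5, 0.4, 0.6)),
               class = "okncs_config_error")
})

test_that("outcome likelihood is the zero-asymptote Weibull on the grid", {
  # at the candidate threshold itself the outcome is a coin flip
  expect_equal(outcome_likelihood(0.05, 0.05, 2), 0.5)
  expect_equal(outcome_likelihood(0.2, 0.2, 0.5), 0.5)
  # vanishing contrast: no guesses
  expect_lt(outcome_likelihood(1e-8, 0.05, 2), 1e-6)
  # increasing in contrast (strictly until double precision saturates at 1)
  p <- outcome_likelihood(ladder, 0.05, 2)
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(p[p < 1 - 1e-12]) > 0))
})

test_that("posterior updates commute and ignore uninformative evidence", {
  seq1 <- list(c(ladder[10], "seen"), c(ladder[20], "not_seen"),
               c(ladder[15], "seen"), c(ladder[30], "seen"))
  apply_seq <- function(ord) {
    q <- quest_init()
    for (i in ord) {
      q <- quest_update(q, as.numeric(seq1[[i]][1]), seq1[[i]][2])
    }
    q$posterior
  }
  expect_equal(apply_seq(1:4), apply_seq(c(3, 1, 4, 2)), tolerance = 1e-12)

  # posterior always renormalized
  q <- quest_init()
  for (i in 1:4) q <- quest_update(q, as.numeric(seq1[[i]][1]), seq1[[i]][2])
  expect_equal(sum(q$posterior), 1, tolerance = 1e-12)

  expect_error(quest_update(quest_init(), 0.1234, "seen"),
               class = "okncs_config_error")
})

test_that("posterior equals the brute-force product-of-likelihoods oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n_trials <- sample(1:6, 1)
    hist <- data.frame(
      contrast = sample(ladder, n_trials, replace = TRUE),
      outcome = sample(c("seen", "not_seen"), n_trials, replace = TRUE))
    q <- quest_init()
    for (r in seq_len(n_trials)) {
      q <- quest_update(q, hist$contrast[r], hist$outcome[r])
    }
    want <- oracle_quest_posterior(ladder, slopes, hist)
    expect_equal(q$posterior, want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("contrast selection minimizes expected entropy (enumeration oracle)", {
  # random posteriors: selection must match full enumeration
  set.seed(88)
  for (rep in 1:6) {
    q <- quest_init()
    n_up <- sample(2:5, 1)
    for (i in 1:n_up) {
      q <- quest_update(q, sample(ladder, 1),
                        sample(c("seen", "not_seen"), 1))
    }
    got <- quest_next_contrast(q, details = TRUE)
    want_eh <- oracle_expected_entropies(ladder, slopes, q$posterior)
    expect_equal(got$expected_entropy, want_eh, tolerance = 1e-9)
    expect_equal(got$contrast, ladder[which.min(want_eh)])
    # argmin property is assertable directly
    eh_sel <- got$expected_entropy[match(got$contrast, ladder)]
    expect_true(all(eh_sel <= got$expected_entropy + 1e-12))
  }
})

test_that("a concentrated posterior selects a level at its threshold", {
  # an exactly degenerate posterior has zero entropy whatever the outcome,
  # so every level ties and the documented tie-break (lowest contrast) wins
  prior <- matrix(0, 39, 11)
  prior[17, 6] <- 1
  expect_equal(quest_next_contrast(quest_init(prior = prior)), ladder[1])

  # concentrated (but not degenerate) posteriors: the minimum sits where
  # outcome uncertainty is informative, near the dominant threshold
  for (j in c(5, 17, 30)) {
    w <- dnorm(seq_len(39), j, 1.5)
    q <- quest_init(prior = matrix(rep(w, 11), 39, 11))
    sel <- quest_next_contrast(q)
    want_eh <- oracle_expected_entropies(ladder, slopes, q$posterior)
    expect_equal(sel, ladder[which(want_eh <= min(want_eh) + 1e-12)[1]])
    expect_lte(abs(log(sel) - log(ladder[j])),
               2 * median(diff(log(ladder))))
  }

  # symmetric posterior over two thresholds: the selected level lies
  # between them (inclusive), by the same enumeration oracle
  prior2 <- matrix(1e-9, 39, 11)
  prior2[c(12, 22), 6] <- 0.5
  q2 <- quest_init(prior = prior2)
  sel2 <- quest_next_contrast(q2)
  eh2 <- oracle_expected_entropies(ladder, slopes, q2$posterior)
  expect_equal(sel2, ladder[which(eh2 <= min(eh2) + 1e-12)[1]])
  expect_gte(sel2, ladder[12])
  expect_lte(sel2, ladder[22])
})

test_that("posterior summaries match direct marginal computations", {
  prior <- matrix(0, 39, 11)
  prior[12, 3] <- 1
  est <- quest_estimate(quest_init(prior = prior))
  expect_equal(est$log_threshold$mode, log(ladder[12]))
  expect_equal(est$slope$mode, slopes[3])
  expect_equal(est$log_threshold$mean, log(ladder[12]))

  # symmetric two-cell posterior: mean is the log-space midpoint
  prior2 <- matrix(0, 39, 11)
  prior2[c(10, 20), 5] <- 0.5
  est2 <- quest_estimate(quest_init(prior = prior2))
  expect_equal(est2$log_threshold$mean,
               mean(log(ladder[c(10, 20)])))

  # mode matches a dense argmax oracle on random posteriors
  set.seed(99)
  for (rep in 1:10) {
    q <- quest_init(prior = matrix(runif(429), 39, 11))
    est <- quest_estimate(q)
    ij <- which(q$posterior == max(q$posterior), arr.ind = TRUE)[1, ]
    expect_equal(est$log_threshold$mode, log(ladder[ij[1]]))
    expect_equal(est$slope$mode, slopes[ij[2]])
  }
})

test_that("mean posterior entropy decreases across adaptive trials", {
  set.seed(111)
  n_runs <- 100
  n_trials <- 16
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  traj <- matrix(NA_real_, n_runs, n_trials + 1)
  for (r in seq_len(n_runs)) {
    true_t <- sample(ladder, 1)
    true_s <- sample(slopes, 1)
    q <- quest_init()
    traj[r, 1] <- H(as.vector(q$posterior))
    for (i in seq_len(n_trials)) {
      x <- quest_next_contrast(q)
      p <- outcome_likelihood(x, true_t, true_s)
      out <- if (runif(1) < p) "seen" else "not_seen"
      q <- quest_update(q, x, out)
      traj[r, i + 1] <- H(as.vector(q$posterior))
    }
  }
  mean_traj <- colMeans(traj)
  expect_true(all(diff(mean_traj) < 0.02))  # non-increasing within noise
  expect_lt(mean_traj[n_trials + 1], mean_traj[1] - 1)
})

test_that("64 adaptive trials recover grid-member observers", {
  set.seed(123)
  n_runs <- 200
  err <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    true_t <- sample(ladder[5:35], 1)  # interior thresholds
    true_s <- sample(slopes, 1)
    q <- quest_init()
    for (i in 1:64) {
      x <- quest_next_contrast(q)
      out <- if (runif(1) < outcome_likelihood(x, true_t, true_s))
        "seen" else "not_seen"
      q <- quest_update(q, x, out)
    }
    err[r] <- abs(quest_estimate(q)$log_threshold$mode - log(true_t))
  }
  half_step <- median(diff(log(ladder))) / 2
  expect_lt(median(err), half_step)
})

test_that("quest state serializes to a readable audit log", {
  q <- quest_init()
  q <- quest_update(q, contrast_ladder()[20], "seen")
  f <- tempfile(fileext = ".json")
  quest_serialize(q, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$ladder, q$ladder)
  expect_equal(matrix(unlist(back$posterior), 39, 11, byrow = FALSE),
               q$posterior, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$history$contrast, q$history$contrast)
})
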