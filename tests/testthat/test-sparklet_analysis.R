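test_that("idealization maps signals to quantal levels", {
  qc <- quantal_config(quantal_amplitude = 1, max_levels = 5)

  flat <- sparklet_trace(rep(0, 200))
  rec <- detect_and_idealize(flat, qc)
  expect_true(all(rec$levels == 0L))
  expect_equal(rec$n_levels_reached, 0L)

  # noiseless half-open trace: level-1 occupancy of 0.5
  tr <- sparklet_trace(rep(c(1, 0), each = 100))
  rec2 <- detect_and_idealize(tr, qc)
  expect_equal(mean(rec2$levels == 1L), 0.5)

  # half-amplitude decision boundaries
  tr3 <- sparklet_trace(c(0.49, 0.51, 1.49, 1.51))
  expect_equal(detect_and_idealize(tr3, qc)$levels, c(0L, 1L, 1L, 2L))

  bad <- sparklet_trace(rep(0, 5), frame = c(1, 2, 4, 8, 16))
  expect_error(detect_and_idealize(bad, qc), "uniform")
})

test_that("idealization reaches 95% frame accuracy at SNR 5", {
  sim <- gen_sparklet_trace(sparklet_spec(3, 0.4, 0.1, quantal_amplitude = 1,
                                          noise_sd = 0.2, duration = 20,
                                          seed = 11))
  rec <- detect_and_idealize(sim$trace, quantal_config(1, max_levels = 3))
  agreement <- mean(rec$levels == sim$record$levels)
  expect_gte(agreement, 0.95)
})

test_that("nPs is the time-weighted mean level with a strict 0.2 cutoff", {
  expect_equal(compute_nps(idealized_record(rep(0, 100)))$nPs, 0)
  expect_equal(compute_nps(idealized_record(rep(0, 100)))$activity_class,
               "low")

  # one channel open 7% of frames: low-activity site
  lv <- c(rep(1L, 70), rep(0L, 930))
  act <- compute_nps(idealized_record(lv))
  expect_equal(act$nPs, 0.07)
  expect_equal(act$activity_class, "low")

  # level 2 for 10% and level 1 for 10%: nPs 0.30, high activity
  lv2 <- c(rep(2L, 100), rep(1L, 100), rep(0L, 800))
  act2 <- compute_nps(idealized_record(lv2))
  expect_equal(act2$nPs, 0.30)
  expect_equal(act2$activity_class, "high")

  # the boundary itself is low; just above is high
  at <- compute_nps(idealized_record(c(rep(1L, 200), rep(0L, 800))))
  expect_equal(at$nPs, 0.2)
  expect_equal(at$activity_class, "low")
  above <- compute_nps(idealized_record(c(rep(1L, 201), rep(0L, 799))))
  expect_equal(above$activity_class, "high")

  # noiseless round trip: idealized nPs equals the generator's ground truth
  sim <- gen_sparklet_trace(sparklet_spec(3, 0.6, 0.1, noise_sd = 0,
                                          duration = 10, seed = 2))
  rec <- detect_and_idealize(sim$trace, quantal_config(1, max_levels = 3))
  expect_identical(rec$levels, sim$record$levels)
  expect_equal(compute_nps(rec)$nPs, mean(sim$record$levels))
})

test_that("the coupled kernel is a proper Markov transition law", {
  for (k in c(0, 0.3, 1)) {
    P <- coupled_transition_matrix(4, 0.15, k)
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # kappa = 1 reaches only the empty and full levels
  P1 <- coupled_transition_matrix(3, 0.1, 1)
  expect_true(all(P1[, 2:3] == 0))
  pi1 <- stationary_distribution(coupled_transition_matrix(2, 0.2, 0))
  # independent channels: stationary level law is Binomial(N, p)
  expect_equal(pi1, stats::dbinom(0:2, 2, 0.2), tolerance = 1e-8)
})

test_that("kappa estimation recovers coupling and flags N = 1", {
  est0 <- kappa_recovery_mean(0, n_seeds = 5)
  expect_lte(est0, 0.05)
  est1 <- kappa_recovery_mean(1, n_seeds = 5)
  expect_gte(est1, 0.95)

  sim <- gen_sparklet_trace(sparklet_spec(1, 0.5, 0.1, duration = 10,
                                          seed = 1))
  est <- estimate_kappa(sim$record, 1)
  expect_false(est$identifiable)
  expect_true(is.na(est$kappa))

  short <- idealized_record(rep(0L, 50))
  expect_error(estimate_kappa(short, 3), "too short")
  expect_error(estimate_kappa(idealized_record(rep(2L, 200)), 1), "levels")

  # estimates always land in [0, 1]
  for (s in 1:5) {
    simr <- gen_sparklet_trace(sparklet_spec(3, runif(1), 0.1, duration = 5,
                                             seed = s))
    k <- estimate_kappa(simr$record, 3)$kappa
    expect_gte(k, 0)
    expect_lte(k, 1)
  }
})

test_that("kappa error shrinks with record length", {
  rmse_at <- function(frames) {
    err <- vapply(1:6, function(s) {
      sim <- gen_sparklet_trace(sparklet_spec(3, 0.4, 0.1, noise_sd = 0,
                                              duration = frames / 100,
                                              seed = 100 + s))
      estimate_kappa(sim$record, 3)$kappa - 0.4
    }, numeric(1))
    sqrt(mean(err^2))
  }
  r <- c(rmse_at(500), rmse_at(2000), rmse_at(8000))
  expect_lt(r[2], r[1])
  expect_lt(r[3], r[2])
})

test_that("site summaries stratify by class and count silent cells", {
  low <- compute_nps(idealized_record(c(rep(1L, 70), rep(0L, 930))))
  high <- compute_nps(idealized_record(c(rep(1L, 250), rep(0L, 750))))
  s <- site_summary(list(cell1 = list(low, high)))
  expect_equal(s$sites_per_cell, c(cell1 = 2L))
  expect_equal(s$mean_nps_low, 0.07)
  expect_equal(s$mean_nps_high, 0.25)

  # silent cells contribute nPs = 0 to the all-site mean
  s2 <- site_summary(list(list(high), list()))
  expect_equal(s2$sites_per_cell, c(1L, 0L))
  expect_equal(s2$mean_nps_all, mean(c(0.25, 0)))
  expect_true(is.na(s2$mean_nps_low))

  s3 <- site_summary(list(list(low), list(low, high), list(low, low, high)))
  expect_equal(s3$mean_sites_per_cell, 2)
})

test_that("quantal amplitude calibration finds the level spacing", {
  set.seed(3)
  levels <- sample(0:3, 4000, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
  signal <- levels * 1.8 + rnorm(4000, 0, 0.15)
  q <- fit_quantal_amplitude(signal, max_levels = 4)
  expect_lt(abs(q - 1.8) / 1.8, 0.1)
})
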