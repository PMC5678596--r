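test_that("RER follows its closed form and error contracts", {
  expect_equal(rer(100, 100, 0, 1), 0)
  expect_equal(rer(100, 100 * exp(0.2), 0, 1), 0.2)
  expect_equal(rer(200, 100, 0, 2), -log(2) / 2)
  expect_error(rer(0, 100, 0, 1), "non-positive")
  expect_error(rer(100, 100, 1, 1), "differ")
})

test_that("RER is antisymmetric, time-shift, scale and unit invariant", {
  set.seed(12)
  for (k in 1:20) {
    a <- runif(1, 10, 500); b <- runif(1, 10, 500)
    t1 <- runif(1, 0, 5); t2 <- t1 + runif(1, 0.1, 3)
    expect_equal(rer(a, b, t1, t2), -rer(b, a, t1, t2))
    expect_equal(rer(a, b, t1 + 7, t2 + 7), rer(a, b, t1, t2))
    expect_equal(rer(3 * a, 3 * b, t1, t2), rer(a, b, t1, t2))
    px <- 1 / 0.25^2  # px <-> mm2 conversion cancels in the log ratio
    expect_equal(rer(a * px, b * px, t1, t2), rer(a, b, t1, t2))
  }
})

test_that("daily RER recovers r exactly on noiseless exponential growth", {
  s <- simulate_pra_series(r = 0.15, n_days = 3)
  per <- simulated_periods(n_days = 3)
  d <- daily_rer(s, per)
  expect_equal(nrow(d), 3L)
  expect_true(all(abs(d$rer_per_day - 0.15) < 1e-9))

  cst <- simulate_pra_series(r = 0, n_days = 2)
  expect_true(all(abs(daily_rer(cst, simulated_periods(2))$rer_per_day) < 1e-12))
})

test_that("daily RER is unbiased under multiplicative observation noise", {
  # independent error model: each endpoint carries iid log-noise of sd
  # noise_cv, so a daily RER over a light period of length dt has
  # sd = noise_cv * sqrt(2) / dt, and the mean of n_days values shrinks by
  # sqrt(n_days); the estimate must sit within 4 of these sds of r
  per <- simulated_periods(n_days = 3)
  dt <- 35 * 20 / 1440  # light-period endpoint span, days
  for (pid in 1:6) {
    s <- simulate_pra_series(r = 0.15, n_days = 3, noise_cv = 0.02,
                             plant_id = pid, seed = 400 + pid)
    d <- daily_rer(s, per)
    bound <- 4 * 0.02 * sqrt(2) / dt / sqrt(3)
    expect_lt(abs(mean(d$rer_per_day) - 0.15), bound)
  }
  # at the sub-percent noise the imaging pipeline actually delivers, the
  # recovery lands within 10% of r
  for (pid in 1:6) {
    s <- simulate_pra_series(r = 0.15, n_days = 3, noise_cv = 0.003,
                             plant_id = pid, seed = 500 + pid)
    d <- daily_rer(s, per)
    expect_lt(abs(mean(d$rer_per_day) - 0.15) / 0.15, 0.10)
  }
})

test_that("diel RER with the default 10-frame window is exact on exponentials", {
  s <- simulate_pra_series(r = 0.25, n_days = 1)
  d <- diel_rer(s)  # default window
  expect_equal(unique(d$window_frames), 10L)
  expect_true(all(abs(d$rer_per_day - 0.25) < 1e-9))

  cst <- simulate_pra_series(r = 0, n_days = 1)
  expect_true(all(abs(diel_rer(cst)$rer_per_day) < 1e-12))

  short <- simulate_pra_series(r = 0.1, n_days = 1)[1:8, ]
  expect_error(diel_rer(short), "shorter")
})

test_that("multi-day averages are arithmetic means of daily values", {
  s <- simulate_pra_series(r = 0.15, n_days = 6, noise_cv = 0.02, seed = 7)
  d <- daily_rer(s, simulated_periods(6))
  av <- average_daily_rer(d, days = 3)
  expect_equal(nrow(av), 2L)
  expect_equal(av$rer_per_day[1], mean(d$rer_per_day[1:3]))
  expect_equal(av$rer_per_day[2], mean(d$rer_per_day[4:6]))
})

test_that("a WT-like series shows a dawn dip and a dip-free series does not", {
  per <- simulated_periods(3)
  wt <- simulate_pra_series(r = 0.20, n_days = 3, noise_cv = 0.02,
                            dip_amplitude = 0.10, seed = 31)
  dips <- detect_dawn_dip(wt, per)
  expect_gte(sum(dips$dip), 2)
  # smoothed PRA has its within-window minimum after, not at, lights-on
  expect_true(all(dips$t_min[dips$dip] %% 1 > 0))

  mut <- simulate_pra_series(r = 0.08, n_days = 3, noise_cv = 0.02,
                             dip_amplitude = 0, seed = 32)
  expect_equal(sum(detect_dawn_dip(mut, per)$dip), 0L)
})

test_that("series with long gaps are split and short gaps interpolated", {
  s <- simulate_pra_series(r = 0.2, n_days = 1)
  s$missing[20:21] <- TRUE  # short gap: bridged
  d <- diel_rer(s)
  expect_gt(nrow(d), 40)
  s2 <- simulate_pra_series(r = 0.2, n_days = 1)
  s2$missing[30:35] <- TRUE  # long gap: split into two segments
  d2 <- diel_rer(s2)
  gap_t <- s2$time_days[30:35]
  expect_false(any(d2$time_days >= min(gap_t) & d2$time_days <= max(gap_t)))
})
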