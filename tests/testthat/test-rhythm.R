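test_that("pair phases: identity, alternation, quarter-cycle shift", {
  ref <- seq(0, 40, by = 4)
  expect_true(all(pair_phases(ref, ref)$phase_deg == 0))
  expect_true(all(pair_phases(ref, ref + 2)$phase_deg == 180))
  expect_true(all(pair_phases(ref, ref + 1)$phase_deg == 90))
  ph <- pair_phases(ref, ref + 2)
  expect_equal(attr(ph, "n_skipped"), 0L)
  expect_equal(nrow(ph), length(ref) - 1)
})

test_that("cycles without a target onset are skipped and counted", {
  ref <- c(0, 4, 8, 12, 16)
  tar <- c(2, 10, 14) # nothing in [4, 8)
  ph <- pair_phases(ref, tar)
  expect_equal(nrow(ph), 3)
  expect_equal(attr(ph, "n_skipped"), 1L)
  expect_true(all(ph$phase_deg == 180))
})

test_that("disjoint spans yield an empty sample with a warning", {
  expect_warning(ph <- pair_phases(c(0, 1, 2), c(10, 11)), "disjoint")
  expect_equal(nrow(ph), 0)
})

test_that("circular statistics handle concentration, symmetry and wrap", {
  cs <- circular_stats(rep(180, 10))
  expect_equal(cs$mean_deg, 180)
  expect_equal(cs$R, 1)
  expect_equal(cs$circ_sd_deg, 0)

  sym <- circular_stats(rep(c(0, 180), 20))
  expect_lt(sym$R, 1e-8)
  expect_true(is.na(sym$mean_deg))

  wrap <- circular_stats(c(359, 1, 359, 1))
  expect_lt(min(wrap$mean_deg, 360 - wrap$mean_deg), 1e-6)

  expect_error(circular_stats(90), "at least 2")
})

test_that("a von Mises phase sample recovers its preferred direction", {
  set.seed(41)
  deg <- rvonmises(500, mu = 196 * pi / 180, kappa = 4) * 180 / pi
  cs <- circular_stats(deg)
  expect_lt(abs(cs$mean_deg - 196), 5)
  expect_lt(cs$rayleigh_p, 1e-6)
})

test_that("Rayleigh p is calibrated for uniform and concentrated samples", {
  set.seed(42)
  unif_p <- replicate(50, circular_stats(runif(30, 0, 360))$rayleigh_p)
  expect_gt(mean(unif_p > 0.05), 0.8)
  conc <- circular_stats(rnorm(30, 180, 10))
  expect_lt(conc$rayleigh_p, 1e-4)
  # Monte Carlo p agrees with the series approximation at moderate n
  set.seed(43)
  x <- runif(8, 0, 360)
  p_asy <- circular_stats(x)$rayleigh_p
  p_sim <- circular_stats(x, method = "simulation", n_sim = 4000)$rayleigh_p
  expect_lt(abs(p_asy - p_sim), 0.05)
})

test_that("cross-correlogram: self, negation, antiphase sinusoids", {
  set.seed(44)
  env <- random_envelope(4000)
  self <- cross_correlogram(env, env, max_lag_s = 5)
  mid <- which(self$corr$lag_s == 0)
  expect_equal(self$corr$coef[mid], 1, tolerance = 1e-9)
  expect_equal(self$peak_lag_s, 0)
  expect_gt(self$ccc_index, 0)

  neg <- new_trace(-env$value, rate = trace_rate(env))
  opp <- cross_correlogram(env, neg, max_lag_s = 5)
  expect_equal(opp$corr$coef[mid], -1, tolerance = 1e-9)

  rate <- 100; f <- 0.5
  t <- seq(0, 400 - 1 / rate, by = 1 / rate)
  x <- new_trace(sin(2 * pi * f * t), rate = rate)
  y <- new_trace(sin(2 * pi * f * t - pi), rate = rate)
  xc <- cross_correlogram(x, y, max_lag_s = 1.5, cycle_period_s = 2)
  expect_equal(abs(xc$peak_lag_s), 1, tolerance = 0.02)
  analytic <- -cos(2 * pi * f * xc$corr$lag_s)
  expect_lt(max(abs(xc$corr$coef - analytic)), 1e-3)
  expect_lt(xc$corr$coef[xc$corr$lag_s == 0], -0.999)

  expect_error(cross_correlogram(
    new_trace(rep(1, 100), 10), new_trace(rnorm(100), 10)), "variance")
})

test_that("ccc index of independent noise envelopes is near zero", {
  set.seed(45)
  idx <- replicate(40, {
    a <- envelope(new_trace(rnorm(16000), 400), resample_rate = 100)
    b <- envelope(new_trace(rnorm(16000), 400), resample_rate = 100)
    cross_correlogram(a, b, max_lag_s = 3, cycle_period_s = 4)$ccc_index
  })
  expect_lt(mean(abs(idx)), 0.1) # individual draws scatter ~1/sqrt(T/tau)
  expect_lt(abs(mean(idx)), 0.05)
})

test_that("autocorrelation finds the cycle period of a rhythmic envelope", {
  cfg <- sim_config(seed = 46, duration_s = 120)
  sim <- simulate_ventral_roots(cfg)
  ac <- autocorr_rhythmicity(envelope(sim$traces$RL2), max_lag_s = 12)
  expect_lt(abs(ac$period_s - 4), 0.1)
  expect_gt(ac$index, 0.5)
  expect_true(ac$rhythmic)

  set.seed(47)
  noise <- new_trace(abs(rnorm(5000)), rate = 200)
  acn <- autocorr_rhythmicity(noise, max_lag_s = 10)
  expect_lt(acn$index, 0.1)

  expect_error(autocorr_rhythmicity(new_trace(rep(2, 100), 10)), "constant")
})

test_that("frequency modes: degenerate, bimodal and unimodal samples", {
  one <- frequency_modes(rep(0.2, 10), bandwidth = 0.02)
  expect_equal(length(one$modes), 1)
  expect_lt(abs(one$modes - 0.2), 0.005)
  expect_equal(max(one$density$density), 1)

  set.seed(48)
  mix <- c(rnorm(1000, 0.16, 0.02), rnorm(1000, 0.27, 0.02))
  mix <- mix[mix > 0]
  fm <- frequency_modes(mix, bandwidth = 0.02)
  expect_equal(length(fm$modes), 2)
  expect_lt(abs(fm$modes[1] - 0.16), 0.01)
  expect_lt(abs(fm$modes[2] - 0.27), 0.01)

  set.seed(49)
  uni <- frequency_modes(rnorm(1500, 0.22, 0.02), bandwidth = 0.02)
  expect_equal(length(uni$modes), 1)
  expect_lt(abs(uni$modes - 0.22), 0.01)

  expect_error(frequency_modes(c(0.1, 0.2)), "at least 5")
})

test_that("mode detection ignores sample order and uniform duplication", {
  set.seed(50)
  x <- c(rnorm(400, 0.16, 0.02), rnorm(400, 0.27, 0.02))
  x <- x[x > 0]
  base <- frequency_modes(x, bandwidth = 0.02)
  shuffled <- frequency_modes(sample(x), bandwidth = 0.02)
  doubled <- frequency_modes(rep(x, 2), bandwidth = 0.02)
  expect_equal(base$modes, shuffled$modes)
  expect_equal(base$modes, doubled$modes, tolerance = 1e-12)
  expect_equal(base$density$density, doubled$density$density,
               tolerance = 1e-12)
})

test_that("KS comparison matches a direct ECDF oracle and is calibrated", {
  x <- c(1, 2, 3, 4)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(51)
  a <- runif(100)
  b <- runif(100, 0.5, 1.5)
  kt <- ks_compare(a, b)
  expect_equal(kt$statistic, oracle_ks_d(a, b), tolerance = 1e-12)
  expect_lt(abs(kt$statistic - 0.5), 0.12)
  expect_lt(kt$p.value, 1e-6)
  expect_equal(tidy(kt)$p.value, kt$p.value)

  # null p-values are roughly uniform; D is lattice-valued at n = 200 so the
  # null p distribution is slightly lumpy, hence calibration-style bounds
  # rather than a strict uniformity test
  set.seed(52)
  ps <- replicate(500, {
    ks_compare(rnorm(200), rnorm(200))$p.value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.15)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})
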