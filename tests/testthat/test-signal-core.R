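test_that("trace construction validates and timestamps samples", {
  tr <- new_trace(c(0, 1, 2, 3), rate = 2, channel = "RL2", t0 = 10)
  expect_s3_class(tr, "fl_trace")
  expect_equal(tr$time, c(10, 10.5, 11, 11.5))
  expect_equal(trace_rate(tr), 2)
  expect_equal(trace_channel(tr), "RL2")
  expect_error(new_trace(c(1, NA, 2), rate = 1), "finite")
  expect_error(new_trace(1, rate = 1), "at least 2")
  expect_error(new_trace(c(1, 2), rate = 0), "positive")
  lab <- parse_root_label(c("RL2", "LL5", "weird"))
  expect_equal(lab$side, c("R", "L", NA))
  expect_equal(lab$segment, c("L2", "L5", NA))
})

test_that("rectification is the absolute value and preserves metadata", {
  tr <- new_trace(c(-1, 2, -3), rate = 10, channel = "LL5", t0 = 1)
  r <- rectify(tr)
  expect_equal(r$value, c(1, 2, 3))
  expect_equal(trace_rate(r), 10)
  expect_equal(trace_channel(r), "LL5")
  expect_equal(trace_t0(r), 1)

  nonneg <- new_trace(c(0, 1, 0.5, 2), rate = 10)
  expect_equal(rectify(nonneg)$value, nonneg$value)
})

test_that("rectified zero-mean noise recovers the folded-normal mean", {
  set.seed(101)
  tr <- new_trace(rnorm(1e5), rate = 1000)
  m <- mean(rectify(tr)$value)
  expect_lt(abs(m - sqrt(2 / pi)) / sqrt(2 / pi), 0.01)
})

test_that("Hamming smoothing matches the direct weighted-sum oracle", {
  set.seed(7)
  x <- rnorm(400)
  tr <- new_trace(x, rate = 100)
  sm <- smooth_wcma(tr, 21)
  expect_lt(max(abs(sm$value - oracle_wcma(x, 21))), 1e-12)

  # constant in, constant out (normalized weights), incl. edges
  const <- new_trace(rep(3.7, 50), rate = 10)
  expect_equal(smooth_wcma(const, 11)$value, rep(3.7, 50))

  # unit impulse reproduces the normalized window
  imp <- new_trace(c(rep(0, 10), 1, rep(0, 10)), rate = 10)
  out <- smooth_wcma(imp, 5)$value
  k <- 0:4
  w <- 0.54 - 0.46 * cos(2 * pi * k / 4)
  expect_equal(out[9:13], w / sum(w), tolerance = 1e-12)

  expect_error(smooth_wcma(tr, 4), "odd")
  expect_error(smooth_wcma(tr, 401), "odd integer in")
})

test_that("smoothing is linear and shift-covariant on random inputs", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(200)
    y <- rnorm(200)
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    tr_mix <- new_trace(a * x + b * y, rate = 50)
    sm_mix <- smooth_wcma(tr_mix, 15)$value
    sm_sep <- a * smooth_wcma(new_trace(x, 50), 15)$value +
      b * smooth_wcma(new_trace(y, 50), 15)$value
    expect_lt(max(abs(sm_mix - sm_sep)), 1e-10)
  }
})

test_that("resampling preserves identity, constants and sine amplitude", {
  tr <- new_trace(rnorm(100), rate = 100)
  expect_equal(resample_uniform(tr, 100)$value, tr$value)

  const <- new_trace(rep(2, 1000), rate = 1000)
  down <- resample_uniform(const, 100)
  expect_equal(trace_rate(down), 100)
  expect_true(all(abs(down$value - 2) < 1e-9))

  t <- seq(0, 2, by = 1e-4) # 10 kHz
  sine <- new_trace(sin(2 * pi * 5 * t), rate = 1e4)
  rs <- resample_uniform(sine, 1000)
  # compare against the analytic sine on the interior (edge transients trimmed)
  mid <- rs$time > 0.1 & rs$time < 1.9
  amp <- max(abs(rs$value[mid]))
  expect_lt(abs(amp - 1), 0.01)
  expect_lt(max(abs(rs$value[mid] - sin(2 * pi * 5 * rs$time[mid]))), 0.01)

  expect_error(resample_uniform(tr, -5), "positive")
})

test_that("envelope equals its stages composed, and is nonnegative", {
  set.seed(9)
  tr <- new_trace(rnorm(5000), rate = 1000, channel = "RL2")
  env <- envelope(tr, resample_rate = 200, window_s = 0.25)
  wl <- envelope_provenance(env)$window_len
  by_hand <- resample_uniform(
    smooth_wcma(rectify(detrend_median(tr)), wl), 200)
  expect_identical(env$value, pmax(by_hand$value, 0))
  expect_true(all(env$value >= 0))
  expect_s3_class(env, "fl_envelope")
  prov <- envelope_provenance(env)
  expect_true(prov$rectified)
  expect_equal(prov$resample_rate, 200)

  zero <- new_trace(rep(0, 1000), rate = 1000)
  expect_true(all(envelope(zero)$value == 0))
})

test_that("envelope half-max crossings sit near true square-burst edges", {
  # 0.25 Hz square bursts, duty 0.4, no noise: edges known exactly
  rate <- 1000
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  on_times <- seq(2, 38, by = 4)
  gate <- rowSums(sapply(on_times, function(o) t >= o & t < o + 1.6))
  tr <- new_trace(gate, rate = rate)
  window_s <- 0.25
  env <- envelope(tr, resample_rate = 200, window_s = window_s,
                  detrend = FALSE)
  half <- max(env$value) / 2
  up <- env$time[which(diff(env$value > half) == 1)]
  expect_equal(length(up), length(on_times))
  expect_true(all(abs(up - on_times) <= window_s / 2))
})

test_that("random envelopes stay nonnegative for arbitrary inputs", {
  set.seed(10)
  for (i in 1:10) {
    tr <- new_trace(rnorm(800, mean = runif(1, -2, 2)), rate = 400)
    expect_true(all(envelope(tr, resample_rate = 100)$value >= 0))
  }
})

test_that("trace file round trip is exact in samples and metadata", {
  set.seed(11)
  traces <- list(
    RL2 = new_trace(rnorm(500), rate = 250, channel = "RL2"),
    LL2 = new_trace(rnorm(500), rate = 250, channel = "LL2")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(traces, path, meta = list(genotype = "control",
                                         prep_id = "p1"))
  back <- read_traces(path)
  expect_identical(back$RL2$value, traces$RL2$value)
  expect_identical(back$LL2$value, traces$LL2$value)
  expect_equal(trace_rate(back$RL2), 250)
  expect_equal(attr(back, "meta")$genotype, "control")
})
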