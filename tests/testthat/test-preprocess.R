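# Preprocessing chain: gap repair, Hampel, zero-phase low-pass, beat
# detection/averaging, resampling and normalization.

test_that("spline repair reproduces smooth signals through long gaps", {
  n <- 400
  x <- uniform_signal(0.01 * (1:n)^2 - 0.3 * (1:n), dt = 0.01)
  mask <- rep(FALSE, n); mask[200:205] <- TRUE
  rep1 <- spline_repair(x, mask)
  expect_equal(signal_values(rep1)[200:205], x$values[200:205],
               tolerance = 1e-9)
  # empty mask is the identity
  expect_identical(signal_values(spline_repair(x, rep(FALSE, n))), x$values)
})

test_that("spline repair of a slow sinusoid matches an independent spline", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- uniform_signal(sin(2 * pi * 0.1 * t), dt = 0.01)
  mask <- rep(FALSE, length(t)); mask[1000:1009] <- TRUE
  rep1 <- signal_values(spline_repair(x, mask))[1000:1009]
  expect_lt(max(abs(rep1 - x$values[1000:1009])), 1e-4)
  # independent spline oracle through the same support points
  valid <- which(!mask)
  oracle <- pracma::cubicspline(valid, x$values[valid], 1000:1009)
  expect_lt(max(abs(rep1 - oracle)), 1e-6)
})

test_that("spline repair refuses boundary gaps and leaves short runs alone", {
  x <- uniform_signal(rnorm(100), dt = 0.1)
  mask <- rep(FALSE, 100); mask[1:6] <- TRUE
  expect_error(spline_repair(x, mask), "boundary")
  mask2 <- rep(FALSE, 100); mask2[50:52] <- TRUE   # short run: untouched
  expect_identical(signal_values(spline_repair(x, mask2)), x$values)
})

test_that("Hampel replaces spikes on constants and is idempotent on ramps", {
  x <- uniform_signal(c(rep(5, 30), 5 + 25, rep(5, 30)), dt = 0.1)
  x$values[31] <- 30
  h <- hampel_filter(x)
  expect_equal(signal_values(h), rep(5, 61))
  ramp <- uniform_signal(seq(0, 10, length.out = 200), dt = 0.1)
  expect_equal(signal_values(hampel_filter(ramp)), ramp$values)
  expect_error(hampel_filter(uniform_signal(1:5, 1), window_halfwidth = 10),
               "window larger")
})

test_that("Hampel matches a brute-force sliding-median oracle on noisy data", {
  set.seed(31)
  n <- 1000
  clean <- 2 * sin(2 * pi * (1:n) / 150)
  x <- clean + runif(n, -0.3, 0.3)   # bounded noise: no natural outliers
  spikes <- seq(100L, 946L, by = 94L)
  x[spikes] <- x[spikes] + sample(c(-1, 1), 10, TRUE) * 5 * sd(x)
  h <- hampel_filter(uniform_signal(x, 0.01), window_halfwidth = 10, n_mad = 3)
  flagged <- attr(h, "replaced")
  # brute-force oracle
  k <- 10; oracle <- integer(0)
  for (i in (k + 1):(n - k)) {
    w <- x[(i - k):(i + k)]
    med <- median(w)
    if (abs(x[i] - med) > 3 * 1.4826 * median(abs(w - med)))
      oracle <- c(oracle, i)
  }
  expect_identical(flagged, oracle)
  expect_true(all(spikes %in% flagged))
  expect_equal(length(setdiff(flagged, spikes)), 0)
})

test_that("zero-phase filter preserves the passband with no lag", {
  s <- tone(1, 100, 10)
  f <- lowpass_zero_phase(s, 20)
  mid <- 200:800
  expect_lt(abs(max(f$values[mid]) - 1), 0.01)
  cc <- ccf(s$values[mid], f$values[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stopband attenuation beats the analog eighth-order bound", {
  s <- tone(40, 100, 10)
  f <- lowpass_zero_phase(s, 20)
  amp <- max(abs(f$values[200:800]))
  # two passes of an analog 4th-order Butterworth at 2x cutoff:
  # (1 / sqrt(1 + 2^8))^2
  expect_lt(amp, 1 / (1 + 2^8))
  dc <- uniform_signal(rep(3, 500), dt = 0.01)
  expect_equal(lowpass_zero_phase(dc, 20)$values, rep(3, 500),
               tolerance = 1e-6)
  expect_error(lowpass_zero_phase(s, 60), "Nyquist")
})

test_that("beat detection recovers the generator's schedule", {
  spec <- synthetic_cohort_spec(1, postures = "lay", duration_s = 60,
                                heart_rate_hz = 1.2, noise_sd = 0.05,
                                outlier_rate = 0, hrv_frac = 0, seed = 14)
  bp <- generate_bp(spec, 1, "lay")
  filtered <- lowpass_zero_phase(bp, 20)
  beats <- detect_beats(filtered)
  n <- length(beats$beat_times)
  expect_true(abs(n - 72) <= 2)   # 60 s at 1.2 Hz, minus boundary margins
  rate <- 1 / mean(diff(beats$beat_times))
  expect_lt(abs(rate - 1.2) / 1.2, 0.01)
  # landmark times vs the generator's scheduled upstrokes (ground truth)
  ups <- attr(bp, "upstroke_times")
  matched <- vapply(beats$beat_times, function(bt)
    min(abs(bt - ups)), 0)
  expect_lt(stats::median(matched), 0.02)
})

test_that("beat averaging matches the analytic cycle mean", {
  spec <- synthetic_cohort_spec(1, postures = "lay", duration_s = 60,
                                heart_rate_hz = 1, noise_sd = 0,
                                outlier_rate = 0, hrv_frac = 0, seed = 15)
  bp <- generate_bp(spec, 1, "lay")
  beats <- detect_beats(lowpass_zero_phase(bp, 20))
  avg <- beat_average(bp, beats)
  # analytic cycle mean = baseline (raised-cosine bump mean folded in)
  expect_lt(abs(mean(avg$mean_values) - attr(bp, "cycle_mean")) /
              attr(bp, "cycle_mean"), 0.01)
  const <- uniform_signal(rep(7, length(bp$values)), dt = bp$dt)
  avg_c <- beat_average(const, beats)
  expect_equal(avg_c$mean_values, rep(7, length(avg_c$mean_values)))
})

test_that("resampling preserves linear trends and sample counts", {
  bt <- seq(0.5, 299.5, by = 0.97)
  lin <- beat_series(bt, data.frame(upstroke = seq_along(bt),
                                    max = seq_along(bt), min = seq_along(bt)),
                     mean_values = 2 + 0.01 * bt)
  r <- resample_uniform(lin, 0.4)
  expect_equal(signal_values(r), 2 + 0.01 * signal_time(r), tolerance = 1e-9)
  expect_true(abs(length(r$values) - 748) <= 1)  # (299.5 - 0.5) / 0.4 + 1
  expect_error(resample_uniform(lin, -1), "positive")
})

test_that("min-max normalization hits [-1, 1] exactly and is idempotent", {
  s <- uniform_signal(c(0, 5, 10), dt = 1)
  n1 <- minmax_normalize(s)
  expect_equal(signal_values(n1), c(-1, 0, 1))
  expect_equal(signal_values(minmax_normalize(n1)), signal_values(n1))
  already <- uniform_signal(c(-1, 0.3, 1), dt = 1)
  expect_equal(signal_values(minmax_normalize(already)), already$values)
  expect_error(minmax_normalize(uniform_signal(rep(2, 5), 1)), "degenerate")
})

test_that("pipeline on noise-free data reproduces the generator beat means", {
  spec <- synthetic_cohort_spec(1, postures = "lay", duration_s = 120,
                                heart_rate_hz = 1.1, noise_sd = 0,
                                outlier_rate = 0, seed = 16)
  rec <- generate_recording(spec, 1, "lay")
  prep <- preprocess_recording(rec$bp, rec$bfv)
  expect_lt(abs(mean(prep$p_beat$values) - 74.96) / 74.96, 0.02)
  expect_lt(abs(mean(prep$v_beat$values) - 59.27) / 59.27, 0.02)
  expect_equal(1 / prep$p$dt, 2.5)
  expect_equal(range(signal_values(prep$p)), c(-1, 1))
})
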