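test_that("envelope basics: zero in, zero out; nonzero input normalized to 1", {
  z <- pcg_signal(rep(0, 2^13), 2000)
  expect_true(all(envelope_d4d5(z) == 0))
  gen <- generate_clean_pcg(pcg_spec(duration = 5, seed = 2))
  env <- envelope_d4d5(gen$signal)
  expect_equal(max(env), 1)
  expect_equal(length(env), length(gen$signal$samples))
})

test_that("envelope maxima align with ground-truth events within 20 ms", {
  gen <- generate_clean_pcg(pcg_spec(duration = 10, heart_rate = 85, seed = 3))
  env <- envelope_d4d5(gen$signal)
  fs <- 2000
  events <- sort(c(gen$truth$s1_times, gen$truth$s2_times))
  for (tt in events) {
    i0 <- round(tt * fs) + 1
    win <- max(1, i0 - 40):min(length(env), i0 + 40)
    local_max <- win[which.max(env[win])]
    # a true local peak: envelope at event dominates its neighbourhood
    expect_lt(abs((local_max - 1) / fs - tt), 0.02)
  }
})

test_that("cycle detection recovers count and S1/S2 identity on a known PCG", {
  gen <- generate_clean_pcg(pcg_spec(duration = 10, heart_rate = 72, seed = 2))
  seg <- detect_cycles(envelope_d4d5(gen$signal), 2000)
  expect_gte(length(seg$s1_peaks), 10)
  fs <- 2000
  s1_det <- (seg$s1_peaks - 1) / fs
  s2_det <- (seg$s2_peaks - 1) / fs
  ok_s1 <- sapply(s1_det, function(tt) min(abs(tt - gen$truth$s1_times)) < 0.03)
  ok_s2 <- sapply(s2_det, function(tt) min(abs(tt - gen$truth$s2_times)) < 0.03)
  expect_gte(mean(ok_s1), 0.95)
  expect_gte(mean(ok_s2), 0.95)
})

test_that("detected systole fraction tracks the generator setting", {
  gen <- generate_clean_pcg(pcg_spec(duration = 10, heart_rate = 60,
                                     systole_fraction = 0.35, seed = 3))
  seg <- detect_cycles(envelope_d4d5(gen$signal), 2000)
  sys <- mean(seg$s2_peaks - seg$s1_peaks)
  dia <- mean(seg$csv_intervals[, 2] - seg$csv_intervals[, 1])
  expect_lt(abs(sys / (sys + dia) - 0.35), 0.05)
})

test_that("degenerate envelopes raise the no-cycles error", {
  expect_error(detect_cycles(rep(0, 1000), 2000), "no cycles")
  expect_error(detect_cycles(c(rep(0, 100), 1, rep(0, 100)), 2000), "no cycles")
})

test_that("segmentation is deterministic and cycle counts track ground truth", {
  set.seed(77)
  hrs <- stats::runif(12, 60, 160)
  for (hr in hrs) {
    # faster hearts have proportionally shorter valve sounds
    wscale <- min(1, 140 / hr)
    gen <- generate_clean_pcg(pcg_spec(duration = 8, heart_rate = hr,
                                       s1_width = 0.025 * wscale,
                                       s2_width = 0.020 * wscale,
                                       seed = round(hr)))
    env <- envelope_d4d5(gen$signal)
    seg1 <- detect_cycles(env, 2000)
    seg2 <- detect_cycles(env, 2000)
    expect_identical(seg1$s1_peaks, seg2$s1_peaks)
    expect_lte(abs(length(seg1$s1_peaks) - length(gen$truth$s1_times)), 2)
  }
})

test_that("features on a degenerate constant systolic segment", {
  x <- pcg_signal(rep(0.5, 4000), 2000)
  seg <- structure(list(
    s1_peaks = c(500L, 2000L), s2_peaks = c(1000L, 2500L),
    cav_intervals = cbind(start = c(500L, 2000L), end = c(1000L, 2500L)),
    csv_intervals = cbind(start = c(1000L, 2500L), end = c(2000L, 3500L)),
    fs = 2000), class = "cycle_segmentation")
  f <- extract_features(x, seg)
  expect_equal(f[["cav_max"]], 0.5)
  expect_equal(f[["cav_min"]], 0.5)
  expect_equal(f[["cav_mean_abs"]], 0.5)
})

test_that("a sinusoidal systole yields mean |x| = 2/pi and the right PSD peak", {
  fs <- 2000
  t <- (0:3999) / fs
  x <- pcg_signal(sin(2 * pi * 100 * t), fs)
  seg <- structure(list(
    s1_peaks = 1L, s2_peaks = 2001L,
    cav_intervals = cbind(start = 1L, end = 2000L),
    csv_intervals = cbind(start = 2001L, end = 4000L),
    fs = fs), class = "cycle_segmentation")
  f <- extract_features(x, seg)
  expect_equal(f[["cav_mean_abs"]], 2 / pi, tolerance = 0.01)
  v <- x$samples[1:2000]
  ps <- pcgdenoise:::periodogram_hann(v, fs)
  freq_at_max <- (which.max(ps) - 1) * fs / length(v)
  expect_lt(abs(freq_at_max - 100), 2)
})

test_that("feature polarity behaviour: abs/PSD features invariant, max/min swap", {
  gen <- generate_clean_pcg(pcg_spec(duration = 8, seed = 5))
  seg <- detect_cycles(envelope_d4d5(gen$signal), 2000)
  f_pos <- extract_features(gen$signal, seg)
  flipped <- pcg_signal(-gen$signal$samples, 2000)
  f_neg <- extract_features(flipped, seg)
  expect_equal(f_neg[["cav_mean_abs"]], f_pos[["cav_mean_abs"]])
  expect_equal(f_neg[["cav_psd_max"]], f_pos[["cav_psd_max"]])
  expect_equal(f_neg[["csv_psd_mean"]], f_pos[["csv_psd_mean"]])
  expect_equal(f_neg[["cav_max"]], -f_pos[["cav_min"]])
  expect_equal(f_neg[["cav_min"]], -f_pos[["cav_max"]])
})

test_that("a murmur raises the systolic PSD features, paired construction", {
  base <- pcg_spec(duration = 8, heart_rate = 80, seed = 9)
  with_m <- pcg_spec(duration = 8, heart_rate = 80, seed = 9,
                     murmur = list(band_lo = 100, band_hi = 300, amplitude = 0.4))
  g0 <- generate_clean_pcg(base)
  g1 <- generate_clean_pcg(with_m)
  s0 <- segment_pcg(g0$signal)
  s1 <- segment_pcg(g1$signal)
  expect_gt(s1$features[["cav_psd_max"]], s0$features[["cav_psd_max"]])
  expect_gt(s1$features[["cav_mean_abs"]] / s1$features[["csv_mean_abs"]],
            s0$features[["cav_mean_abs"]] / s0$features[["csv_mean_abs"]])
})
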