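test_that("event counts follow duration and heart rate", {
  gen <- generate_clean_pcg(pcg_spec(duration = 10, heart_rate = 60))
  expect_length(gen$truth$s1_times, 10)
  expect_length(gen$truth$s2_times, 10)
  # interleaving: each S2 between consecutive S1s
  expect_true(all(gen$truth$s2_times > gen$truth$s1_times))
  expect_true(all(diff(gen$truth$s1_times) > 0))
})

test_that("spectral peak sits at the S1 frequency for a murmur-free PCG", {
  gen <- generate_clean_pcg(pcg_spec(duration = 10, heart_rate = 80, s1_freq = 60))
  expect_lt(abs(spectral_peak_hz(gen$signal$samples, 2000) - 60), 3)
})

test_that("zero-amplitude murmur equals no murmur under the same seed", {
  a <- generate_clean_pcg(pcg_spec(seed = 4))
  b <- generate_clean_pcg(pcg_spec(
    murmur = list(band_lo = 100, band_hi = 300, amplitude = 0), seed = 4))
  expect_identical(a$signal$samples, b$signal$samples)
})

test_that("overlapping S1/S2 envelopes are rejected", {
  expect_error(
    generate_clean_pcg(pcg_spec(heart_rate = 200, s1_width = 0.08, s2_width = 0.08)),
    "overlap")
})

test_that("ground-truth event times align with the local envelope maxima", {
  gen <- generate_clean_pcg(pcg_spec(duration = 8, heart_rate = 95, seed = 2))
  x <- abs(gen$signal$samples)
  fs <- 2000
  for (tt in c(gen$truth$s1_times, gen$truth$s2_times)) {
    i0 <- round(tt * fs) + 1
    win <- max(1, i0 - 60):min(length(x), i0 + 60)   # +/- 30 ms
    peak_t <- (win[which.max(x[win])] - 1) / fs
    expect_lt(abs(peak_t - tt), 0.005)
  }
})

test_that("Gaussian noise hits the requested SNR exactly", {
  x <- generate_clean_pcg(pcg_spec())$signal
  for (snr in c(0, 5, 10)) {
    y <- add_gaussian_noise(x, snr, seed = 7)
    realized <- 10 * log10(mean(x$samples^2) / mean((y$samples - x$samples)^2))
    expect_equal(realized, snr, tolerance = 1e-10)
  }
  expect_identical(add_gaussian_noise(x, 5, seed = 1)$samples,
                   add_gaussian_noise(x, 5, seed = 1)$samples)
  expect_error(add_gaussian_noise(pcg_signal(numeric(10) + 0, 100), 5),
               "zero-power")
})

test_that("impulse noise adds the scheduled number of clicks and amp 0 is identity", {
  x <- generate_clean_pcg(pcg_spec(duration = 5))$signal
  y <- add_impulse_noise(x, period = 0.5, amp = 1, width = 0.005, seed = 3)
  d <- abs(y$samples - x$samples)
  # count disjoint activity windows in the difference signal
  active <- d > 1e-12
  events <- sum(diff(c(FALSE, active)) == 1)
  expect_equal(events, 10)
  expect_identical(add_impulse_noise(x, amp = 0)$samples, x$samples)
  expect_error(add_impulse_noise(x, period = 0.01, width = 0.02), "smaller")
})

test_that("impulse clicks are broadband: energy above 200 Hz jumps at click instants", {
  x <- generate_clean_pcg(pcg_spec(duration = 5))$signal
  y <- add_impulse_noise(x, period = 0.5, amp = 1.5, width = 0.005, seed = 3)
  fs <- 2000
  hi_energy <- function(sig, i0, w = 64) {
    seg <- sig[(i0 - w):(i0 + w)]
    sp <- abs(stats::fft(seg))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    sum(sp[f > 200 & f < 1000])
  }
  i_click <- round(0.25 * fs) + 1
  gain_db <- 10 * log10(hi_energy(y$samples, i_click) / hi_energy(x$samples, i_click))
  expect_gte(gain_db, 10)
})

test_that("crying bursts are local, band-limited and reproducible", {
  x <- generate_clean_pcg(pcg_spec(duration = 6, heart_rate = 60))$signal
  y <- add_crying_bursts(x, burst_times = 3.2, burst_dur = 0.8, amp = 2, seed = 5)
  d <- y$samples - x$samples
  t <- (seq_along(d) - 1) / 2000
  expect_true(all(d[t < 3.2 | t > 4.0] == 0))
  expect_true(any(d[t > 3.25 & t < 3.95] != 0))
  expect_identical(add_crying_bursts(x, 3.2, amp = 0)$samples, x$samples)
  expect_error(add_crying_bursts(x, burst_times = 5.9, burst_dur = 0.5),
               "outside")
})

test_that("crying bursts raise Mel energies only in filters at or above 155 Hz", {
  x <- generate_clean_pcg(pcg_spec(duration = 6, heart_rate = 60))$signal
  y <- add_crying_bursts(x, burst_times = c(1, 3), burst_dur = 1,
                         band = c(155, 500), amp = 3, seed = 5)
  me_x <- mel_energies(x, log = FALSE)
  me_y <- mel_energies(y, log = FALSE)
  rise <- me_y - me_x                          # linear band energies add
  hi <- attr(me_x, "f_lower") >= 155
  # the burst gate's 20 ms ramps spread the band edge by ~50 Hz, so the
  # "untouched" region starts safely below that spread
  lo <- attr(me_x, "f_upper") <= 110
  expect_gt(min(rise[hi]), 0)                  # every in-band filter elevated
  expect_lt(max(rise[lo]), 0.05 * min(rise[hi]))
})
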