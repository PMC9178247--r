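#' Specification of a synthetic pediatric phonocardiogram
#'
#' Describes one simulated recording: periodic S1/S2 valve-closure transients
#' modelled as Gaussian-enveloped sinusoids, an optional systolic murmur
#' (band-limited noise confined to the S1->S2 interval), and a heart rate.
#' Defaults emulate a quiet pediatric recording whose spectral energy is
#' dominated by the 30-200 Hz band: S1 centred at 50 Hz (25 ms envelope),
#' S2 at 75 Hz (20 ms) — the dominant components of the two valve-closure
#' sounds, S2 sitting higher and shorter than S1 — and systole 35% of the
#' cycle.
#'
#' @param duration Record length in seconds (> 0).
#' @param heart_rate Beats per minute, in \[30, 220\].
#' @param s1_freq,s2_freq Dominant frequency of each transient, Hz.
#' @param s1_width,s2_width Gaussian envelope standard deviation, seconds.
#' @param s1_amp,s2_amp Relative amplitudes of the two transients.
#' @param systole_fraction S1->S2 gap as a fraction of the cycle, in (0, 1).
#' @param murmur \code{NULL} for none, or a list with \code{band_lo},
#'   \code{band_hi} (Hz) and \code{amplitude} (relative to S1 peak).
#' @param seed Integer seed controlling the murmur noise realization.
#' @return An object of class \code{"pcg_spec"}.
#' @export
pcg_spec <- function(duration = 10, heart_rate = 90,
                     s1_freq = 50, s2_freq = 75,
                     s1_width = 0.025, s2_width = 0.020,
                     s1_amp = 1, s2_amp = 0.8,
                     systole_fraction = 0.35,
                     murmur = NULL, seed = 1L) {
  stopifnot(duration > 0, heart_rate >= 30, heart_rate <= 220,
            systole_fraction > 0, systole_fraction < 1,
            s1_width > 0, s2_width > 0, s1_freq > 0, s2_freq > 0)
  if (!is.null(murmur)) {
    stopifnot(is.list(murmur),
              all(c("band_lo", "band_hi", "amplitude") %in% names(murmur)),
              murmur$band_lo > 0, murmur$band_hi > murmur$band_lo,
              murmur$amplitude >= 0)
  }
  structure(list(duration = duration, heart_rate = heart_rate,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 s1_width = s1_width, s2_width = s2_width,
                 s1_amp = s1_amp, s2_amp = s2_amp,
                 systole_fraction = systole_fraction,
                 murmur = murmur, seed = as.integer(seed)),
            class = "pcg_spec")
}

#' @export
print.pcg_spec <- function(x, ...) {
  cat(sprintf("<pcg_spec> %.1f s @ %g bpm, S1 %g Hz / S2 %g Hz, systole %.0f%%%s\n",
              x$duration, x$heart_rate, x$s1_freq, x$s2_freq,
              100 * x$systole_fraction,
              if (is.null(x$murmur)) "" else
                sprintf(", murmur %g-%g Hz (amp %g)",
                        x$murmur$band_lo, x$murmur$band_hi, x$murmur$amplitude)))
  invisible(x)
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# zero-phase ideal band-pass by FFT masking (both spectral sides)
bandpass_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency magnitude
  mask <- as.numeric(f >= lo & f <= hi)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Generate a clean synthetic PCG with ground truth
#'
#' S1 events are placed at cycle starts (after a 0.1 s lead-in), S2 events at
#' \code{systole_fraction} of each cycle; each is a Gaussian-enveloped
#' sinusoid. An optional murmur adds band-limited noise inside every S1->S2
#' interval. The waveform is peak-normalized to 0.9.
#'
#' @param spec A \code{pcg_spec}.
#' @param fs Sampling rate in Hz (default 2000, the working rate).
#' @return A list with \code{signal} (a \code{pcg_signal}) and \code{truth}
#'   (list with \code{s1_times}, \code{s2_times} in seconds and \code{clean},
#'   the same signal — kept as the reference for evaluation).
#' @export
generate_clean_pcg <- function(spec, fs = 2000) {
  stopifnot(inherits(spec, "pcg_spec"))
  if (spec$s1_freq >= fs / 2 || spec$s2_freq >= fs / 2)
    stop("transient frequency must be below fs/2")
  cycle <- 60 / spec$heart_rate
  systole <- spec$systole_fraction * cycle
  diastole <- cycle - systole
  if (3 * (spec$s1_width + spec$s2_width) >= systole)
    stop("S1/S2 envelopes overlap: widen systole or narrow the transients")
  if (3 * spec$s2_width >= diastole)
    stop("S2 envelope spills into the next cycle")

  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  lead_in <- 0.1
  s1_times <- seq(lead_in, spec$duration - 1 / fs, by = cycle)
  s2_times <- s1_times + systole
  s2_times <- s2_times[s2_times < spec$duration]
  s1_times <- s1_times[seq_along(s2_times)]  # keep cycles complete

  transient <- function(t0, f0, w, a) {
    a * exp(-(t - t0)^2 / (2 * w^2)) * sin(2 * pi * f0 * (t - t0))
  }
  x <- numeric(n)
  for (t0 in s1_times) x <- x + transient(t0, spec$s1_freq, spec$s1_width, spec$s1_amp)
  for (t0 in s2_times) x <- x + transient(t0, spec$s2_freq, spec$s2_width, spec$s2_amp)

  if (!is.null(spec$murmur) && spec$murmur$amplitude > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(n))
    noise <- bandpass_fft(noise, fs, spec$murmur$band_lo, spec$murmur$band_hi)
    gate <- numeric(n)
    ramp <- 0.01
    for (i in seq_along(s1_times)) {
      gate <- gate + window_gate(t, s1_times[i], s2_times[i], ramp)
    }
    gate <- pmin(gate, 1)
    noise <- noise / max(abs(noise))
    x <- x + spec$murmur$amplitude * spec$s1_amp * noise * gate
  }
  x <- 0.9 * x / max(abs(x))
  sig <- pcg_signal(x, fs)
  list(signal = sig,
       truth = list(s1_times = s1_times, s2_times = s2_times, clean = sig))
}

# cosine-ramped rectangular gate on [t0, t1]
window_gate <- function(t, t0, t1, ramp) {
  g <- numeric(length(t))
  core <- t >= (t0 + ramp) & t <= (t1 - ramp)
  up <- t >= t0 & t < (t0 + ramp)
  dn <- t > (t1 - ramp) & t <= t1
  g[core] <- 1
  g[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  g[dn] <- 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  g
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' The realized noise sequence is rescaled after drawing so that
#' \code{10*log10(P_signal / P_noise)} equals \code{snr_db} exactly,
#' not merely in expectation.
#'
#' @param x A \code{pcg_signal} with nonzero power.
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed for the noise realization.
#' @return A \code{pcg_signal} of the same length and rate.
#' @export
add_gaussian_noise <- function(x, snr_db, seed = 1L) {
  stopifnot(inherits(x, "pcg_signal"))
  p_sig <- mean(x$samples^2)
  if (p_sig == 0) stop("cannot set an SNR on a zero-power signal")
  e <- with_seed(seed, stats::rnorm(length(x$samples)))
  e <- e * sqrt(p_sig / (mean(e^2) * 10^(snr_db / 10)))
  pcg_signal(x$samples + e, x$fs)
}

#' Add periodic impulsive interference
#'
#' Short broadband clicks (Hann-windowed white noise of width \code{width})
#' are added every \code{period} seconds, emulating friction/contact noise.
#'
#' @param x A \code{pcg_signal}.
#' @param period Spacing between impulses, seconds (> \code{width}).
#' @param amp Click amplitude relative to the signal's peak amplitude.
#' @param width Click duration, seconds.
#' @param seed Integer seed.
#' @return A \code{pcg_signal}.
#' @export
add_impulse_noise <- function(x, period = 0.5, amp = 1, width = 0.005, seed = 1L) {
  stopifnot(inherits(x, "pcg_signal"), period > 0, width > 0)
  if (width >= period) stop("impulse width must be smaller than the period")
  if (amp == 0) return(x)
  n <- length(x$samples)
  fs <- x$fs
  dur <- n / fs
  centers <- seq(period / 2, dur - width, by = period)
  wlen <- max(3L, round(width * fs))
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
  peak <- max(abs(x$samples))
  y <- x$samples
  clicks <- with_seed(seed, matrix(stats::rnorm(wlen * length(centers)), nrow = wlen))
  for (i in seq_along(centers)) {
    i0 <- round(centers[i] * fs) + 1L
    idx <- i0:(i0 + wlen - 1L)
    idx <- idx[idx >= 1L & idx <= n]
    c_i <- clicks[seq_along(idx), i] * win[seq_along(idx)]
    y[idx] <- y[idx] + amp * peak * c_i / max(abs(c_i))
  }
  pcg_signal(y, fs)
}

#' Add intermittent crying-like bursts
#'
#' Band-limited noise bursts with cosine on/off ramps, confined to the given
#' burst windows. The default band starts at 155 Hz — above the S1/S2 band,
#' where crying interference manifests — and extends to 950 Hz: a loud
#' infant cry (fundamental 400-600 Hz plus harmonics) carries energy well
#' past the nominal 500 Hz corner of a stethoscope's hardware filter, whose
#' roll-off is gradual, and that out-of-band energy is what drives noise
#' estimators during severe crying.
#'
#' @param x A \code{pcg_signal}.
#' @param burst_times Burst onset times in seconds.
#' @param burst_dur Burst duration in seconds.
#' @param band Two-element frequency band (Hz), default \code{c(155, 950)}.
#' @param amp Burst amplitude relative to the signal's peak amplitude.
#' @param ramp Cosine ramp length in seconds (default 20 ms).
#' @param seed Integer seed.
#' @return A \code{pcg_signal}.
#' @export
add_crying_bursts <- function(x, burst_times, burst_dur = 0.6,
                              band = c(155, 950), amp = 1, ramp = 0.02,
                              seed = 1L) {
  stopifnot(inherits(x, "pcg_signal"), length(band) == 2L, band[1] < band[2])
  if (amp == 0) return(x)
  n <- length(x$samples)
  fs <- x$fs
  dur <- n / fs
  if (any(burst_times < 0) || any(burst_times + burst_dur > dur))
    stop("burst window extends outside the signal")
  t <- (seq_len(n) - 1) / fs
  noise <- with_seed(seed, stats::rnorm(n))
  noise <- bandpass_fft(noise, fs, band[1], min(band[2], fs / 2))
  noise <- noise / max(abs(noise))
  gate <- numeric(n)
  for (t0 in burst_times) gate <- gate + window_gate(t, t0, t0 + burst_dur, ramp)
  gate <- pmin(gate, 1)
  peak <- max(abs(x$samples))
  pcg_signal(x$samples + amp * peak * noise * gate, fs)
}

#' Severe-crying study scenario
#'
#' The package's reference condition for burst-noise experiments: a 10 s
#' murmur-bearing recording (heart rate 90, systolic murmur at relative
#' amplitude 0.3) overlaid with five 1.3 s crying bursts every 2 s (65%
#' duty cycle) at 2.5 times the heart-sound peak — crying loud enough to
#' dominate the waveform during bursts and present most of the time, as in
#' a severely distressed infant.
#'
#' @param seed Integer seed for the noise realization.
#' @param fs Sampling rate (default 2000 Hz).
#' @return List with \code{clean} and \code{noisy} \code{pcg_signal}s.
#' @export
severe_crying_pcg <- function(seed = 1L, fs = 2000) {
  spec <- pcg_spec(duration = 10, heart_rate = 90,
                   murmur = list(band_lo = 100, band_hi = 300, amplitude = 0.3),
                   seed = 5L)
  clean <- generate_clean_pcg(spec, fs)$signal
  noisy <- add_crying_bursts(clean, burst_times = seq(0.3, 8.3, by = 2),
                             burst_dur = 1.3, amp = 2.5, seed = seed)
  list(clean = clean, noisy = noisy)
}

#' Generate a synthetic screening cohort
#'
#' Random per-subject recordings: heart rate drawn uniformly in 70-140
#' beats/min, systole fraction in 0.33-0.42, and — for abnormal subjects —
#' a systolic murmur (100-300 Hz) with relative amplitude drawn in
#' \code{murmur_amp}. Mild recording noise is added at 25 dB SNR so the
#' cohort is not artificially pristine.
#'
#' @param n_normal,n_abnormal Group sizes.
#' @param murmur_amp Range the abnormal-group murmur amplitude is drawn from.
#' @param duration Record length in seconds.
#' @param seed Cohort seed.
#' @param fs Sampling rate.
#' @return List with \code{signals} (list of \code{pcg_signal}),
#'   \code{labels} (0 = normal, 1 = abnormal) and \code{specs}.
#' @export
generate_cohort <- function(n_normal = 37, n_abnormal = 66,
                            murmur_amp = c(0.25, 0.5), duration = 10,
                            seed = 1L, fs = 2000) {
  n <- n_normal + n_abnormal
  labels <- c(rep(0L, n_normal), rep(1L, n_abnormal))
  pars <- with_seed(seed, list(
    hr = stats::runif(n, 70, 140),
    sf = stats::runif(n, 0.33, 0.42),
    ma = stats::runif(n, murmur_amp[1], murmur_amp[2])))
  signals <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    mur <- if (labels[i] == 1L)
      list(band_lo = 100, band_hi = 300, amplitude = pars$ma[i]) else NULL
    specs[[i]] <- pcg_spec(duration = duration, heart_rate = pars$hr[i],
                           systole_fraction = pars$sf[i], murmur = mur,
                           seed = seed * 1000L + i)
    x <- generate_clean_pcg(specs[[i]], fs)$signal
    signals[[i]] <- add_gaussian_noise(x, 25, seed = seed * 2000L + i)
  }
  list(signals = signals, labels = labels, specs = specs)
}
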