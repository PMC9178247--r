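#' Heart-sound envelope from the d4 x d5 Hadamard product
#'
#' Reconstructs the level-4 and level-5 wavelet detail bands to full length
#' (62.5-125 Hz and 31.25-62.5 Hz at the 2 kHz working rate — the bands that
#' straddle S1/S2 energy), takes the absolute value of their elementwise
#' (Hadamard) product, smooths it with a moving average, and normalizes the
#' result to a maximum of 1. S1/S2 transients excite both bands at once, so
#' the product peaks at the valve-closure instants while band-limited
#' interference outside the overlap is suppressed.
#'
#' @param x A \code{pcg_signal}.
#' @param wavelet Wavelet filter (default \code{"db6"}).
#' @param product_levels The two detail levels to multiply (default 4 and 5).
#' @param smooth_win Moving-average window in seconds (default 50 ms).
#' @return Numeric envelope, same length as \code{x}, max 1 (all-zero for a
#'   zero signal).
#' @export
envelope_d4d5 <- function(x, wavelet = "db6", product_levels = c(4, 5),
                          smooth_win = 0.05) {
  stopifnot(inherits(x, "pcg_signal"), length(product_levels) == 2)
  d_a <- wavelet_detail(x$samples, product_levels[1], wavelet)
  d_b <- wavelet_detail(x$samples, product_levels[2], wavelet)
  env <- abs(d_a * d_b)
  w <- max(1L, round(smooth_win * x$fs))
  env <- stats::filter(env, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  if (max(env) > 0) env <- env / max(env)
  env
}

#' Detect heart-sound cycles by double-qualified peak picking
#'
#' Qualification 1: envelope peaks above \code{amp_thresh_frac} with at
#' least \code{peak_min_gap} separation (greedy, loudest first).
#' Qualification 2: alternate-interval labeling — of each adjacent peak
#' pair, the shorter interval (at most \code{systole_max}) is systole, so
#' its leading peak is S1 and its trailing peak S2. Incomplete trailing
#' cycles are dropped.
#'
#' @param envelope Normalized envelope from \code{\link{envelope_d4d5}}.
#' @param fs Sampling rate in Hz.
#' @param amp_thresh_frac Amplitude threshold as a fraction of the envelope
#'   maximum (default 0.2).
#' @param peak_min_gap Minimum peak separation in seconds (default 120 ms).
#' @param systole_max Upper bound on the systolic interval in seconds.
#' @return An object of class \code{"cycle_segmentation"}: list with
#'   \code{s1_peaks}, \code{s2_peaks} (sample indices), \code{cav_intervals}
#'   and \code{csv_intervals} (two-column matrices of start/end samples:
#'   systolic S1->S2 and diastolic S2->next-S1 windows), and \code{fs}.
#' @export
detect_cycles <- function(envelope, fs, amp_thresh_frac = 0.2,
                          peak_min_gap = 0.12, systole_max = 0.5) {
  stopifnot(fs > 0, amp_thresh_frac > 0, amp_thresh_frac < 1)
  env <- as.numeric(envelope)
  n <- length(env)
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  cand <- cand[env[cand] >= amp_thresh_frac * max(env)]
  if (length(cand) > 0) {
    # greedy non-maximum suppression, loudest peak first
    cand <- cand[order(env[cand], decreasing = TRUE)]
    keep <- integer(0)
    min_gap <- round(peak_min_gap * fs)
    for (p in cand) if (all(abs(p - keep) >= min_gap)) keep <- c(keep, p)
    peaks <- sort(keep)
  } else peaks <- integer(0)
  if (length(peaks) < 3L) stop("no cycles: fewer than 3 qualified peaks")

  gaps <- diff(peaks) / fs
  # first interval is systole iff it is the shorter of the first two
  first_sys <- gaps[1] <= gaps[2]
  sys_idx <- if (first_sys) seq(1L, length(gaps), by = 2L)
             else seq(2L, length(gaps), by = 2L)
  sys_idx <- sys_idx[gaps[sys_idx] <= systole_max]
  # complete cycle = systolic gap followed by a diastolic gap
  sys_idx <- sys_idx[sys_idx + 1L <= length(gaps)]
  if (length(sys_idx) == 0L) stop("no cycles: no systolic interval qualified")
  s1 <- peaks[sys_idx]
  s2 <- peaks[sys_idx + 1L]
  next_s1 <- peaks[pmin(sys_idx + 2L, length(peaks))]
  structure(list(s1_peaks = s1, s2_peaks = s2,
                 cav_intervals = cbind(start = s1, end = s2),
                 csv_intervals = cbind(start = s2, end = next_s1),
                 fs = fs),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  sys <- mean((x$s2_peaks - x$s1_peaks) / x$fs)
  dia <- mean((x$csv_intervals[, 2] - x$csv_intervals[, 1]) / x$fs)
  cat(sprintf("<cycle_segmentation> %d cycles, mean systole %.0f ms, mean diastole %.0f ms\n",
              length(x$s1_peaks), 1000 * sys, 1000 * dia))
  invisible(x)
}

#' Extract the 10 systolic/diastolic screening features
#'
#' Per complete cycle: maximum, minimum and mean absolute amplitude in the
#' systolic (CAV, S1->S2) window (features 1-3) and in the diastolic (CSV,
#' S2->next S1) window (features 4-6); maximum and mean power spectral
#' density (Hann-windowed periodogram) of the CAV window (features 7-8) and
#' of the CSV window (features 9-10). Per-cycle values are averaged across
#' cycles. Murmurs raise the systolic amplitude and PSD features, which is
#' what makes the vector discriminative for congenital heart disease.
#'
#' @param x The (denoised) \code{pcg_signal}.
#' @param seg A \code{\link{detect_cycles}} segmentation of \code{x}.
#' @return Named numeric vector of length 10
#'   (\code{cav_max, cav_min, cav_mean_abs, csv_max, csv_min, csv_mean_abs,
#'   cav_psd_max, cav_psd_mean, csv_psd_max, csv_psd_mean}).
#' @export
extract_features <- function(x, seg) {
  stopifnot(inherits(x, "pcg_signal"), inherits(seg, "cycle_segmentation"))
  n_cyc <- length(seg$s1_peaks)
  if (n_cyc == 0L) stop("empty segmentation")
  feat_period <- function(i0, i1) {
    v <- x$samples[i0:i1]
    ps <- periodogram_hann(v, x$fs)
    c(max(v), min(v), mean(abs(v)), max(ps), mean(ps))
  }
  acc <- matrix(0, n_cyc, 10)
  for (i in seq_len(n_cyc)) {
    cav <- feat_period(seg$cav_intervals[i, 1], seg$cav_intervals[i, 2])
    csv <- feat_period(seg$csv_intervals[i, 1], seg$csv_intervals[i, 2])
    acc[i, ] <- c(cav[1:3], csv[1:3], cav[4:5], csv[4:5])
  }
  stats::setNames(colMeans(acc),
                  c("cav_max", "cav_min", "cav_mean_abs",
                    "csv_max", "csv_min", "csv_mean_abs",
                    "cav_psd_max", "cav_psd_mean",
                    "csv_psd_max", "csv_psd_mean"))
}

# one-sided Hann periodogram, power per Hz
periodogram_hann <- function(v, fs) {
  n <- length(v)
  if (n < 4) return(rep(mean(v^2) / fs, 2))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  sp <- abs(stats::fft(v * w))^2 / (fs * sum(w^2))
  sp[seq_len(n %/% 2 + 1)]
}

#' Segment a PCG end to end
#'
#' Convenience wrapper: envelope, cycle detection, feature extraction.
#'
#' @param x A \code{pcg_signal}.
#' @param ... Passed to \code{\link{detect_cycles}}.
#' @return List with \code{segmentation} and \code{features}.
#' @export
segment_pcg <- function(x, ...) {
  env <- envelope_d4d5(x)
  seg <- detect_cycles(env, x$fs, ...)
  list(segmentation = seg, features = extract_features(x, seg))
}
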