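#' Signal-to-noise ratio against a clean reference
#'
#' \code{10 log10(sum(clean^2) / sum((clean - estimate)^2))}. When the two
#' signals are identical the ratio is infinite; the value is capped at the
#' 300 dB sentinel (attribute \code{capped = TRUE}).
#'
#' @param clean,estimate Equal-length \code{pcg_signal}s or numeric vectors.
#' @return SNR in dB.
#' @export
snr_db <- function(clean, estimate) {
  c0 <- signal_samples(clean); e0 <- signal_samples(estimate)
  if (length(c0) != length(e0)) stop("lengths differ")
  p_sig <- sum(c0^2)
  if (p_sig == 0) stop("clean reference has zero power")
  p_err <- sum((c0 - e0)^2)
  if (p_err == 0) return(structure(300, capped = TRUE))
  min(10 * log10(p_sig / p_err), 300)
}

signal_samples <- function(x) {
  if (inherits(x, "pcg_signal")) x$samples else as.numeric(x)
}

#' Root mean square error
#'
#' @param clean,estimate Equal-length signals.
#' @return \code{sqrt(mean((clean - estimate)^2))}, amplitude units.
#' @export
rmse <- function(clean, estimate) {
  c0 <- signal_samples(clean); e0 <- signal_samples(estimate)
  if (length(c0) != length(e0)) stop("lengths differ")
  sqrt(mean((c0 - e0)^2))
}

#' Reference-free denoising ratio (dnSNR)
#'
#' \code{10 log10(P_noisy / P_denoised)} with powers taken as mean squared
#' amplitude — a clean-reference-free indicator of how much energy the
#' denoiser removed. Note the convention: the value grows as more energy
#' (noise or signal) is removed; it is reported, not interpreted.
#'
#' @param noisy The noise-containing input signal.
#' @param denoised The denoised output.
#' @return dnSNR in dB.
#' @export
dn_snr <- function(noisy, denoised) {
  s <- signal_samples(noisy); d <- signal_samples(denoised)
  p_s <- mean(s^2); p_d <- mean(d^2)
  if (p_s == 0) stop("noisy input has zero power")
  if (p_d == 0) stop("denoised signal has zero power")
  10 * log10(p_s / p_d)
}

#' Mel filterbank log energies
#'
#' Triangular filters spaced uniformly on the Mel scale between \code{f_lo}
#' and \code{f_hi} (default 30-500 Hz, the hardware band of the recording
#' stethoscope), applied to Hann-windowed framewise power spectra; log
#' energies are averaged over frames. With the default 24 filters, the 9th
#' filter's band starts near 155 Hz, so crying-type interference (which
#' lives above 155 Hz) elevates filters 9 and up while leaving the S1/S2
#' band untouched.
#'
#' @param x A \code{pcg_signal}.
#' @param n_filters Number of triangular filters (>= 2).
#' @param f_lo,f_hi Filterbank frequency limits in Hz.
#' @param frame_len,frame_hop Frame length and hop, seconds.
#' @param floor_eps Energy floor applied before the log.
#' @param log If \code{TRUE} (default) return frame-averaged log energies
#'   (the usual filterbank display); if \code{FALSE} return frame-averaged
#'   linear energies, which are additive across filters and therefore the
#'   right scale for band-energy comparisons.
#' @return Numeric vector of mean (log) energies, one per filter, with
#'   attributes \code{centers}, \code{f_lower}, \code{f_upper} (Hz).
#' @export
mel_energies <- function(x, n_filters = 24, f_lo = 30, f_hi = 500,
                         frame_len = 0.025, frame_hop = 0.010,
                         floor_eps = 1e-12, log = TRUE) {
  stopifnot(inherits(x, "pcg_signal"), n_filters >= 2,
            f_lo > 0, f_hi > f_lo, f_hi <= x$fs / 2)
  n <- length(x$samples)
  flen <- round(frame_len * x$fs)
  hop <- max(1L, round(frame_hop * x$fs))
  if (flen > n) stop("frame longer than signal")
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)))
  starts <- seq(1L, n - flen + 1L, by = hop)

  nfft <- 2^ceiling(log2(flen))
  fbins <- (0:(nfft %/% 2)) * x$fs / nfft
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(f_lo), mel(f_hi), length.out = n_filters + 2))
  fb <- matrix(0, length(fbins), n_filters)
  for (j in seq_len(n_filters)) {
    lo <- pts[j]; cc <- pts[j + 1]; hi <- pts[j + 2]
    up <- (fbins - lo) / (cc - lo)
    dn <- (hi - fbins) / (hi - cc)
    # area-normalized triangles so wider filters are not favoured
    fb[, j] <- pmax(0, pmin(up, dn)) * 2 / (hi - lo)
  }

  acc <- numeric(n_filters)
  for (s in starts) {
    fr <- x$samples[s:(s + flen - 1L)] * win
    sp <- abs(stats::fft(c(fr, numeric(nfft - flen))))^2
    sp <- sp[seq_along(fbins)]
    en <- pmax(drop(crossprod(fb, sp)), floor_eps)
    acc <- acc + if (log) base::log(en) else en
  }
  structure(acc / length(starts),
            centers = pts[2:(n_filters + 1)],
            f_lower = pts[seq_len(n_filters)],
            f_upper = pts[3:(n_filters + 2)])
}

#' Confusion-matrix screening metrics
#'
#' Accuracy, sensitivity and specificity in percent, rounded to 2 decimals,
#' from binary screening counts (positive = abnormal heart sound).
#'
#' @param tp,tn,fp,fn Nonnegative integer counts; each class must be
#'   represented (\code{tp + fn > 0}, \code{tn + fp > 0}).
#' @return Named numeric vector \code{c(acc, se, sp)} in percent.
#' @examples
#' confusion_metrics(tp = 61, tn = 34, fp = 3, fn = 5)  # 92.23 92.42 91.89
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  cnt <- c(tp, tn, fp, fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be nonnegative integers")
  if (tp + fn == 0) stop("no positive-class samples")
  if (tn + fp == 0) stop("no negative-class samples")
  c(acc = round_half_up(100 * (tp + tn) / sum(cnt), 2),
    se  = round_half_up(100 * tp / (tp + fn), 2),
    sp  = round_half_up(100 * tn / (tn + fp), 2))
}

# conventional half-up rounding, as used in printed tables (round() would
# take 12.385 to 12.38 by round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Clinical benchmark tables of the denoising study
#'
#' Published per-recording evaluation of the four denoisers on eight
#' pediatric PCG recordings (four normal, four with congenital heart
#' disease) contaminated with 5 and 10 dB Gaussian noise: output SNR (dB)
#' and RMSE per recording, noise level and method. Shipped so the study's
#' aggregate figures can be recomputed.
#'
#' @param metric \code{"snr"} or \code{"rmse"}.
#' @return A long-format data frame with columns \code{pcg}, \code{group},
#'   \code{noise_db}, \code{method}, \code{value}.
#' @export
clinical_benchmark <- function(metric = c("snr", "rmse")) {
  metric <- match.arg(metric)
  path <- system.file("extdata",
                      paste0("clinical_benchmark_", metric, ".csv"),
                      package = "pcgdenoise", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate the clinical benchmark table
#'
#' Column means of the benchmark per (method, noise level), plus the
#' normal-recording-only means — the summary figures quoted for the study.
#'
#' @param metric \code{"snr"} or \code{"rmse"}.
#' @return A data frame with columns \code{method}, \code{noise_db},
#'   \code{mean_all}, \code{mean_normal}, each rounded to 2 decimals.
#' @export
benchmark_summary <- function(metric = c("snr", "rmse")) {
  df <- clinical_benchmark(metric)
  agg <- stats::aggregate(value ~ method + noise_db, df, mean)
  nrm <- stats::aggregate(value ~ method + noise_db, df[df$group == "normal", ], mean)
  names(agg)[3] <- "mean_all"
  names(nrm)[3] <- "mean_normal"
  out <- merge(agg, nrm, by = c("method", "noise_db"))
  out$mean_all <- round_half_up(out$mean_all, 2)
  out$mean_normal <- round_half_up(out$mean_normal, 2)
  out[order(out$method, out$noise_db), ]
}
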