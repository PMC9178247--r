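# shared fixtures, all generated in code

tone <- function(freq, dur = 1, fs = 2000, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  pcg_signal(amp * cos(2 * pi * freq * t), fs)
}

two_tone_4s <- function(fs = 2000) {
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  list(t = t,
       x = pcg_signal(cos(2 * pi * 50 * t) + cos(2 * pi * 200 * t), fs),
       lo = cos(2 * pi * 50 * t), hi = cos(2 * pi * 200 * t))
}

# ideal FFT band-split: zero all bins outside [lo, hi] Hz (the independent
# oracle VMD modes are compared against on well-separated tones)
fft_bandsplit <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= lo & f <= hi)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

spectral_peak_hz <- function(x, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * fs / n
}
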