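#' Construct a sampled signal
#'
#' The carrier object used throughout the package: a finite, real-valued
#' amplitude trace together with its sampling rate. Amplitudes are in
#' arbitrary units, nominally within \[-1, 1\] for audio read from PCM WAV.
#'
#' @param samples Numeric vector of amplitudes; must be finite and non-empty.
#' @param fs Sampling rate in Hz; must be a single positive number.
#' @return An object of class \code{"pcg_signal"}: a list with elements
#'   \code{samples} and \code{fs}.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1/500)), fs = 500)
#' s
#' @export
pcg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = as.numeric(fs)), class = "pcg_signal")
}

#' @export
print.pcg_signal <- function(x, ...) {
  cat(sprintf("<pcg_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param x A \code{pcg_signal}.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "pcg_signal"))
  length(x$samples) / x$fs
}

as_pcg_signal <- function(x, fs = NULL) {
  if (inherits(x, "pcg_signal")) return(x)
  if (is.null(fs)) stop("fs required when input is a bare numeric vector")
  pcg_signal(x, fs)
}

#' Resample a signal to a new rate
#'
#' Polyphase rational-ratio resampling with an anti-aliasing filter
#' (via \code{signal::resample}). The rate ratio is approximated by a
#' rational number to within 1e-8 relative error, which is exact for the
#' usual audio rates (e.g. 44100 -> 2000 Hz is 20/441).
#'
#' @param x A \code{pcg_signal}.
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A \code{pcg_signal} at \code{target_fs}. A band-limited component
#'   below \code{target_fs/2} keeps its frequency.
#' @export
resample_signal <- function(x, target_fs) {
  stopifnot(inherits(x, "pcg_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("target_fs must be a single positive number")
  if (isTRUE(all.equal(target_fs, x$fs))) return(x)
  r <- rational_approx(target_fs / x$fs)
  y <- signal::resample(x$samples, p = r[1], q = r[2])
  # pin the output length to the ideal round(n * p / q)
  n_out <- round(length(x$samples) * r[1] / r[2])
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  pcg_signal(y, target_fs)
}

# smallest p/q with |p/q - x| <= tol * x, by continued fractions
rational_approx <- function(x, tol = 1e-8) {
  a <- floor(x); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1; r <- x - a
  while (abs(p1 / q1 - x) > tol * x && q1 < 1e7) {
    r <- 1 / r
    a <- floor(r)
    r <- r - a
    tmp <- p1; p1 <- a * p1 + p0; p0 <- tmp
    tmp <- q1; q1 <- a * q1 + q0; q0 <- tmp
  }
  c(as.integer(p1), as.integer(q1))
}
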