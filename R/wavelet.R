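# Orthogonal wavelet filter bank, periodized boundary handling.
# Periodization keeps the transform orthogonal at every even length, so the
# inverse is exact to machine precision — a property the denoiser's tests
# rely on. Filters are the standard Daubechies coefficients.

.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523),
  db6 = c(-0.00107730108530848, 0.004777257510945511,
          0.0005538422011614961, -0.031582039317486034,
          0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983,
          0.3152503517091976, 0.7511339080210954,
          0.4946238903984533, 0.11154074335010947)
)

wavelet_filter <- function(wavelet) {
  lo <- .wavelet_filters[[wavelet]]
  if (is.null(lo)) stop("unknown wavelet: ", wavelet, " (available: ",
                        paste(names(.wavelet_filters), collapse = ", "), ")")
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror
  list(lo = lo, hi = hi, length = L)
}

# one analysis step: x (even length) -> list(a, d), each length n/2
dwt_step <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(filt$length)) {
    idx <- (base + (j - 1L)) %% n + 1L
    xv <- x[idx]
    a <- a + filt$lo[j] * xv
    d <- d + filt$hi[j] * xv
  }
  list(a = a, d = d)
}

# transpose of dwt_step: exact inverse by orthogonality
idwt_step <- function(a, d, filt) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_len(filt$length)) {
    idx <- (base + (j - 1L)) %% n + 1L
    x[idx] <- x[idx] + filt$lo[j] * a + filt$hi[j] * d
  }
  x
}

#' Multi-level discrete wavelet decomposition
#'
#' Periodized orthogonal DWT. Odd-length inputs at any level are extended by
#' repeating the final sample; the original lengths are recorded so
#' \code{\link{waverec}} restores the input length exactly.
#'
#' @param x Numeric vector.
#' @param wavelet Filter name: \code{"haar"}, \code{"db2"}, \code{"db4"},
#'   \code{"db6"}.
#' @param levels Number of decomposition levels (>= 1); the signal must be
#'   at least \code{2^levels} samples long.
#' @return A list with \code{approx} (coarsest approximation), \code{details}
#'   (list, level 1 = finest first), \code{wavelet}, \code{lengths}.
#' @export
wavedec <- function(x, wavelet = "db6", levels = 6) {
  x <- as.numeric(x)
  stopifnot(levels >= 1)
  if (length(x) < 2^levels)
    stop("signal too short for ", levels, " levels: need >= ", 2^levels, " samples")
  filt <- wavelet_filter(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    st <- dwt_step(a, filt)
    details[[lev]] <- st$d
    a <- st$a
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 lengths = lengths), class = "wavedec")
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' @param wd A \code{wavedec} object (possibly with modified coefficients).
#' @return Numeric vector of the original length.
#' @export
waverec <- function(wd) {
  stopifnot(inherits(wd, "wavedec"))
  filt <- wavelet_filter(wd$wavelet)
  a <- wd$approx
  for (lev in rev(seq_along(wd$details))) {
    a <- idwt_step(a, wd$details[[lev]], filt)
    a <- a[seq_len(wd$lengths[lev])]
  }
  a
}

#' Reconstruct a single detail band to full signal length
#'
#' Zeroes every coefficient band except the requested detail level and
#' inverts the transform, giving the band-limited component of the signal
#' at that scale (level j spans roughly fs/2^(j+1) to fs/2^j).
#'
#' @param x Numeric vector.
#' @param level Detail level to keep (1 = finest).
#' @param wavelet Filter name.
#' @return Numeric vector, same length as \code{x}.
#' @export
wavelet_detail <- function(x, level, wavelet = "db6") {
  wd <- wavedec(x, wavelet, levels = level)
  wd$approx <- numeric(length(wd$approx))
  for (lev in seq_len(level - 1)) wd$details[[lev]] <- numeric(length(wd$details[[lev]]))
  waverec(wd)
}

#' Soft-threshold operator
#'
#' Shrinks a coefficient toward zero by \code{t}, killing it when
#' \code{|value| <= t}: \code{sign(value) * max(|value| - t, 0)}.
#'
#' @param value Coefficient(s).
#' @param t Threshold, >= 0.
#' @return Thresholded coefficient(s).
#' @export
soft_threshold <- function(value, t) {
  if (any(t < 0)) stop("threshold must be nonnegative")
  sign(value) * pmax(abs(value) - t, 0)
}

#' Universal threshold
#'
#' Donoho's threshold \eqn{T = \hat\sigma \sqrt{2 \ln n}} with the noise
#' scale estimated robustly from the finest detail band:
#' \eqn{\hat\sigma = \mathrm{median}(|d_1|) / 0.6745}.
#'
#' @param finest_details Level-1 detail coefficients (nonempty).
#' @param n Total signal length the threshold is calibrated for.
#' @return The threshold value.
#' @export
universal_threshold <- function(finest_details, n) {
  if (length(finest_details) == 0L) stop("no detail coefficients")
  sigma <- stats::median(abs(finest_details)) / 0.6745
  sigma * sqrt(2 * log(n))
}

#' Wavelet soft-threshold denoising
#'
#' The classical recipe: decompose to \code{levels} scales, estimate the
#' noise scale from the finest detail band, soft-threshold every detail
#' coefficient with the universal threshold (one global threshold,
#' calibrated to the full signal length), leave the approximation band
#' untouched so the low-frequency heart-sound content survives, and invert.
#'
#' @param x A \code{pcg_signal} (or numeric vector with \code{fs}).
#' @param wavelet Filter name (default \code{"db6"}).
#' @param levels Decomposition depth (default 6).
#' @param fs Sampling rate when \code{x} is a bare vector.
#' @return A denoised \code{pcg_signal} of the same length.
#' @export
wst_denoise <- function(x, wavelet = "db6", levels = 6, fs = NULL) {
  x <- as_pcg_signal(x, fs)
  wd <- wavedec(x$samples, wavelet, levels)
  thr <- universal_threshold(wd$details[[1]], length(x$samples))
  wd$details <- lapply(wd$details, soft_threshold, t = thr)
  pcg_signal(waverec(wd), x$fs)
}
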