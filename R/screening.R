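#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of a sequence,
#' normalized by \code{log(factorial(m))} so the value lies in \[0, 1\]:
#' 0 for a monotone sequence (one pattern), approaching 1 for i.i.d. noise
#' (all \code{m!} patterns equally likely). Ties are broken by position:
#' of two equal values the earlier one ranks lower, which makes the measure
#' deterministic on quantized audio.
#'
#' @param x Numeric sequence, length at least \code{(m-1)*delay + 2}.
#' @param m Embedding dimension (pattern order), >= 2.
#' @param delay Embedding delay in samples, >= 1.
#' @return Normalized permutation entropy in \[0, 1\].
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), m = 3)  # 0.5888
#' permutation_entropy(1:100, m = 5)                     # 0
#' @export
permutation_entropy <- function(x, m = 5, delay = 1) {
  stopifnot(m >= 2, delay >= 1)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("sequence contains non-finite values")
  n_win <- length(x) - (m - 1) * delay
  if (n_win < 1L) stop("sequence too short for one ordinal window")
  cols <- lapply(seq_len(m), function(j) x[seq.int(1 + (j - 1) * delay,
                                                   by = 1, length.out = n_win)])
  # Lehmer code: c_i = #{j > i : x_j < x_i}, ties resolved by position
  # (x_j == x_i with j > i ranks higher, so it does not count)
  code <- integer(n_win)
  fact <- factorial((m - 1):0)
  for (i in seq_len(m - 1)) {
    ci <- integer(n_win)
    for (j in (i + 1):m) ci <- ci + (cols[[j]] < cols[[i]])
    code <- code + ci * fact[i]
  }
  p <- tabulate(code + 1L, nbins = factorial(m))
  p <- p[p > 0] / n_win
  -sum(p * log(p)) / log(factorial(m))
}

#' Absolute correlation between a mode and the original signal
#'
#' Magnitude of the Pearson correlation coefficient; the sign is discarded
#' because a polarity-flipped mode carries the same information. A constant
#' (zero-variance) input is scored 0 with a warning.
#'
#' @param mode,reference Equal-length numeric sequences.
#' @return Value in \[0, 1\].
#' @export
mode_correlation <- function(mode, reference) {
  mode <- as.numeric(mode); reference <- as.numeric(reference)
  if (length(mode) != length(reference)) stop("lengths differ")
  if (stats::sd(mode) == 0 || stats::sd(reference) == 0) {
    warning("constant input: correlation defined as 0")
    return(0)
  }
  abs(stats::cor(mode, reference))
}

#' Mode screening index
#'
#' Combines the mode-to-signal correlation \code{rsig} and the normalized
#' permutation entropy \code{pec} of a mode into a single noise-propensity
#' score: \code{beta * (1 - rsig) + (1 - beta) * pec}. High values flag
#' modes that are both decorrelated from the signal and pattern-random,
#' i.e. noise.
#'
#' @param rsig Correlation magnitude in \[0, 1\] (vectorized).
#' @param pec Normalized permutation entropy in \[0, 1\] (vectorized).
#' @param beta Propensity weight in \[0, 1\]; the default 0.3 favours the
#'   entropy term.
#' @return The screening index, same length as the inputs.
#' @export
screening_index <- function(rsig, pec, beta = 0.3) {
  if (any(rsig < 0 | rsig > 1) || any(pec < 0 | pec > 1) ||
      beta < 0 || beta > 1)
    stop("rsig, pec and beta must lie in [0, 1]")
  beta * (1 - rsig) + (1 - beta) * pec
}

#' Screen VMD modes for reconstruction
#'
#' Scores every mode of a decomposition by permutation entropy and absolute
#' correlation with the original (pre-denoising) signal, combines the two
#' via \code{\link{screening_index}}, and rejects a mode only when its index
#' exceeds \code{t_rsp} \emph{and} its correlation falls below \code{t_rsig}
#' (defaults 0.6 and 0.5). If the rule would reject every mode, the single
#' mode with the largest correlation is retained instead (with a warning) so
#' reconstruction is always possible.
#'
#' @param fit A \code{vmd} object.
#' @param original The signal that was decomposed (a \code{pcg_signal} or
#'   numeric vector) — the noisy record, since no clean reference exists at
#'   run time.
#' @param beta Propensity weight of \code{\link{screening_index}}.
#' @param t_rsp Index threshold above which a mode is suspect.
#' @param t_rsig Correlation threshold below which a suspect mode is rejected.
#' @param pe_order,pe_delay Permutation-entropy embedding parameters.
#' @return An object of class \code{"mode_scores"}: list with \code{pec},
#'   \code{rsig}, \code{rsp} (per-mode scores), \code{retained} and
#'   \code{rejected} index sets, and \code{fallback} flag.
#' @export
select_modes <- function(fit, original, beta = 0.3, t_rsp = 0.6, t_rsig = 0.5,
                         pe_order = 5, pe_delay = 1) {
  stopifnot(inherits(fit, "vmd"))
  ref <- if (inherits(original, "pcg_signal")) original$samples else as.numeric(original)
  if (length(ref) != nrow(fit$modes)) stop("original and modes have different lengths")
  K <- fit$K
  pec <- vapply(seq_len(K), function(k)
    permutation_entropy(fit$modes[, k], m = pe_order, delay = pe_delay), 0)
  rsig <- vapply(seq_len(K), function(k)
    mode_correlation(fit$modes[, k], ref), 0)
  rsp <- screening_index(rsig, pec, beta)
  reject <- rsp > t_rsp & rsig < t_rsig
  fallback <- all(reject)
  if (fallback) {
    warning("screening rejected every mode; retaining the best-correlated one")
    reject[which.max(rsig)] <- FALSE
  }
  structure(list(pec = pec, rsig = rsig, rsp = rsp,
                 retained = which(!reject), rejected = which(reject),
                 beta = beta, t_rsp = t_rsp, t_rsig = t_rsig,
                 fallback = fallback),
            class = "mode_scores")
}

#' @export
print.mode_scores <- function(x, ...) {
  df <- data.frame(mode = seq_along(x$rsp),
                   pec = round(x$pec, 3), rsig = round(x$rsig, 3),
                   rsp = round(x$rsp, 3),
                   decision = ifelse(seq_along(x$rsp) %in% x$rejected,
                                     "rejected", "retained"))
  cat(sprintf("<mode_scores> beta = %g, reject if rsp > %g & rsig < %g%s\n",
              x$beta, x$t_rsp, x$t_rsig,
              if (x$fallback) " [fallback applied]" else ""))
  print(df, row.names = FALSE)
  invisible(x)
}
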