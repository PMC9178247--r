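#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for integer PCM (8/16/24/32-bit) and IEEE float
#' audio. Multi-channel files are reduced to the first channel (a warning is
#' emitted). Integer samples are scaled to \[-1, 1) by the format's full
#' scale (e.g. 2^15 for 16-bit).
#'
#' @param path Path to an existing WAV file.
#' @return A \code{pcg_signal} at the file's native rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("WAV file has no audio data: ", path)

  bytes <- fmt$bits %/% 8L
  if (fmt$audio_format == 1L) {           # integer PCM
    if (fmt$bits == 8L) {
      x <- (as.numeric(readBin(data_raw, "integer", length(data_raw), 1L,
                               signed = FALSE)) - 128) / 128
    } else if (fmt$bits %in% c(16L, 32L)) {
      x <- readBin(data_raw, "integer", length(data_raw) %/% bytes, bytes,
                   signed = TRUE, endian = "little") / 2^(fmt$bits - 1L)
    } else if (fmt$bits == 24L) {
      n <- length(data_raw) %/% 3L
      m <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$audio_format == 3L) {    # IEEE float
    x <- readBin(data_raw, "double", length(data_raw) %/% bytes, bytes,
                 endian = "little")
  } else stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")

  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV: keeping channel 1 of ", fmt$n_channels)
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  }
  if (length(x) == 0L) stop("zero-length audio in ", path)
  pcg_signal(x, fmt$sample_rate)
}

#' Write a signal as 16-bit PCM WAV
#'
#' Samples are quantized to 16-bit integers with full scale 2^15 (values
#' clipped to the representable range), matching the scaling used by
#' \code{\link{read_wav}}, so a write/read round trip is exact to within
#' one quantization step (2^-15).
#'
#' @param x A \code{pcg_signal}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "pcg_signal"))
  q <- as.integer(pmin(pmax(round(x$samples * 32768), -32768), 32767))
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")              # PCM
  writeBin(1L, con, 2L, endian = "little")              # mono
  writeBin(as.integer(round(x$fs)), con, 4L, endian = "little")
  writeBin(as.integer(round(x$fs)) * 2L, con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4L, endian = "little")
  writeBin(q, con, 2L, endian = "little")
  invisible(path)
}
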