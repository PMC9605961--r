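#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the formats used in voice work: integer PCM
#' (8/16/24/32 bit) and IEEE float (32/64 bit), any channel count. Samples
#' are returned as doubles in \[-1, 1\]. An analysis interval can be cut
#' out by start/end seconds; channels are optionally mean-downmixed.
#'
#' @param path WAV file path.
#' @param start,end interval in seconds (`end = Inf` reads to the end).
#' @param downmix average channels to mono.
#' @return list: `samples` (vector, or matrix with one column per channel
#'   when `downmix = FALSE` and the file is multichannel), `sample_rate`,
#'   `n_channels`, `bit_depth`.
#' @export
read_wav <- function(path, start = 0, end = Inf, downmix = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  bytes <- fmt$bits %/% 8
  n_tot <- length(data_raw) %/% (bytes * fmt$n_channels)
  dec <- function(raw) {
    if (fmt$audio_format == 3L) {          # IEEE float
      readBin(raw, "double", n = length(raw) %/% bytes, size = bytes,
              endian = "little")
    } else if (fmt$bits == 8L) {
      (readBin(raw, "integer", n = length(raw), size = 1,
               signed = FALSE) - 128) / 128
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else {
      readBin(raw, "integer", n = length(raw) %/% bytes, size = bytes,
              signed = TRUE, endian = "little") / 2^(fmt$bits - 1)
    }
  }
  x <- dec(data_raw)
  x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  dur <- n_tot / fmt$sample_rate
  if (start < 0 || start >= end) stop("invalid interval", call. = FALSE)
  i0 <- max(1L, floor(start * fmt$sample_rate) + 1L)
  i1 <- min(n_tot, if (is.finite(end)) ceiling(end * fmt$sample_rate)
                   else n_tot)
  if (i0 > n_tot) stop("interval out of range (file is ",
                       round(dur, 3), " s)", call. = FALSE)
  x <- x[i0:i1, , drop = FALSE]
  samples <- if (downmix || fmt$n_channels == 1L) rowMeans(x) else x
  list(samples = samples, sample_rate = fmt$sample_rate,
       n_channels = fmt$n_channels, bit_depth = fmt$bits)
}

#' Write a mono or multichannel WAV file
#'
#' @param samples numeric vector (mono) or matrix (channel per column),
#'   values in \[-1, 1\] (clipped otherwise).
#' @param path output path.
#' @param sample_rate Hz.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bit_depth = 16L) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  interleaved <- pmin(1, pmax(-1, interleaved))
  bytes <- bit_depth %/% 8L
  data_size <- length(interleaved) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (bit_depth == 32L) 3L else 1L)   # float vs integer PCM
  w16(nch); w32(sample_rate)
  w32(sample_rate * nch * bytes); w16(nch * bytes); w16(bit_depth)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bit_depth == 32L) {
    writeBin(interleaved, con, 4, endian = "little")
  } else {
    # symmetric with the reader's /2^15 so round trips stay within half
    # a quantization step
    writeBin(as.integer(pmax(-32768, pmin(32767,
                                          round(interleaved * 32768)))),
             con, 2, endian = "little")
  }
  invisible(path)
}
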