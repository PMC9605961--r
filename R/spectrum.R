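#' Averaged magnitude spectrum of a sustained-tone interval
#'
#' Long-term average spectrum by Welch's method: the waveform is cut into
#' Hann-windowed frames with 50% overlap, the squared FFT magnitude of each
#' frame is averaged across frames, and the square root of the average is
#' returned as the linear magnitude `S(f)` per bin. All downstream energy
#' sums use `S^2`, so the stored magnitudes carry mean power per bin.
#'
#' @param samples numeric waveform (mono, or a matrix with one channel per
#'   column -- channels are mean-downmixed).
#' @param sample_rate sampling rate in Hz.
#' @param window_length analysis window length in samples (Hann window).
#'   The default 4096 gives ~10.77 Hz bins at 44.1 kHz, far finer than the
#'   1600--2200 Hz wide analysis bands.
#' @param overlap fractional frame overlap in \[0, 1).
#' @param nfft transform length, >= `window_length` (zero-padded if larger).
#' @return object of class `power_spectrum`: `frequencies` (uniform Hz grid
#'   from 0 to Nyquist), `magnitudes` (non-negative `S(f)`), `bin_width`,
#'   and `meta` (sample rate, window, nfft, number of averaged frames).
#' @examples
#' fs <- 44100
#' t <- seq(0, 0.5, by = 1 / fs)
#' sp <- compute_spectrum(sin(2 * pi * 3000 * t), fs)
#' sp$frequencies[which.max(sp$magnitudes)]
#' @export
compute_spectrum <- function(samples, sample_rate, window_length = 4096L,
                             overlap = 0.5, nfft = window_length) {
  samples <- downmix(samples)
  stopifnot(sample_rate > 0, overlap >= 0, overlap < 1,
            nfft >= window_length)
  n <- length(samples)
  if (n < window_length) stop("segment too short", call. = FALSE)
  win <- hann_window(window_length)
  hop <- max(1L, as.integer(round(window_length * (1 - overlap))))
  starts <- seq.int(1L, n - window_length + 1L, by = hop)
  nbins <- nfft %/% 2L + 1L
  acc <- numeric(nbins)
  for (s in starts) {
    frame <- samples[s:(s + window_length - 1L)] * win
    X <- stats::fft(c(frame, numeric(nfft - window_length)))
    acc <- acc + Mod(X[seq_len(nbins)])^2
  }
  pow <- acc / length(starts)
  bw <- sample_rate / nfft
  structure(list(
    frequencies = (seq_len(nbins) - 1L) * bw,
    magnitudes  = sqrt(pow),
    bin_width   = bw,
    meta = list(sample_rate = sample_rate, window = "hann",
                nfft = as.integer(nfft), n_frames = length(starts),
                window_length = as.integer(window_length))
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f Hz/bin, %d frames @ %g Hz\n",
              length(x$frequencies), x$bin_width, x$meta$n_frames,
              x$meta$sample_rate))
  invisible(x)
}

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))
}

# mean-downmix multichannel input to mono
downmix <- function(samples) {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  as.numeric(samples)
}

check_band_nyquist <- function(band, sample_rate) {
  if (sample_rate < 2 * band$b2)
    stop("band exceeds Nyquist", call. = FALSE)
  invisible(TRUE)
}
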