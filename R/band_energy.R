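#' Normalized band energy density and cumulative distribution
#'
#' Restricts a magnitude spectrum to the singer's formant band of a voice
#' type and normalizes the squared magnitudes into an energy density
#' p(f) = S^2(f) / sum_band S^2 and its running sum, the cumulative energy
#' distribution P(f). Band membership is frozen as: bins whose center lies
#' in \[b1, b2) plus the bin containing b2, so that P at the last band bin
#' is exactly 1.
#'
#' @param spectrum a `power_spectrum` from [compute_spectrum()].
#' @param band a `voice_band` (or a voice type name).
#' @return object of class `band_energy_profile`: `band`, `frequencies`
#'   (band-restricted grid), `density`, `cumulative`, `band_energy`
#'   (unnormalized sum of S^2 over the band) and `bin_width`.
#' @export
band_energy_profile <- function(spectrum, band) {
  band <- as_voice_band(band)
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$frequencies
  bw <- spectrum$bin_width
  idx <- band_bin_index(f, bw, band)
  if (length(idx) == 0L)
    stop("band does not overlap spectrum frequency range", call. = FALSE)
  s2 <- spectrum$magnitudes[idx]^2
  total <- sum(s2)
  if (total <= 0) stop("no energy in band", call. = FALSE)
  density <- s2 / total
  structure(list(
    band = band,
    frequencies = f[idx],
    density = density,
    cumulative = cumsum(density),
    band_energy = total,
    bin_width = bw
  ), class = "band_energy_profile")
}

# bins with center in [b1, b2) plus the bin containing b2
band_bin_index <- function(freqs, bin_width, band) {
  inside <- which(freqs >= band$b1 & freqs < band$b2)
  holds_b2 <- which(freqs - bin_width / 2 <= band$b2 &
                    band$b2 < freqs + bin_width / 2)
  sort(unique(c(inside, holds_b2)))
}

#' Frequency of Half Energy (FHE)
#'
#' The frequency at which the cumulative band energy distribution P(f)
#' reaches 0.5: the headline timbre parameter. Higher FHE means a brighter
#' voice. The crossing is located by linear interpolation of P between the
#' last bin with P < 0.5 and the first bin with P >= 0.5, which removes
#' bin-width quantization; if the first band bin already carries half the
#' energy, its center frequency is returned.
#'
#' @param profile a `band_energy_profile`.
#' @return FHE in Hz, guaranteed inside \[b1, b2\].
#' @export
frequency_of_half_energy <- function(profile) {
  stopifnot(inherits(profile, "band_energy_profile"))
  P <- profile$cumulative
  f <- profile$frequencies
  k <- which(P >= 0.5)[1L]
  if (is.na(k)) k <- length(P)       # guard against 1 - eps rounding
  if (k == 1L) return(clamp_band(f[1L], profile$band))
  p0 <- P[k - 1L]; p1 <- P[k]
  fhe <- if (p1 > p0) f[k - 1L] + (0.5 - p0) / (p1 - p0) * (f[k] - f[k - 1L])
         else f[k]
  clamp_band(fhe, profile$band)
}

clamp_band <- function(x, band) min(max(x, band$b1), band$b2)

#' Position of Half Energy (PHE)
#'
#' FHE expressed as a relative position inside the analysis band,
#' `(fhe - b1) / (b2 - b1) * 100`, in percent. PHE makes voices with
#' different band presets comparable and has a larger SD-to-mean ratio
#' than FHE, which benefits downstream classifiers.
#'
#' @param fhe frequency of half energy, Hz.
#' @param band a `voice_band` (or voice type name).
#' @return PHE in percent, in \[0, 100\].
#' @export
position_of_half_energy <- function(fhe, band) {
  band <- as_voice_band(band)
  if (any(fhe < band$b1 | fhe > band$b2))
    stop("FHE outside band", call. = FALSE)
  (fhe - band$b1) / (band$b2 - band$b1) * 100
}

#' Spectral centroid of the band energy density
#'
#' First moment of p(f): the energetic center of the singer's formant band,
#' in Hz. Correlates strongly with perceived brightness.
#'
#' @param profile a `band_energy_profile`.
#' @return SC in Hz.
#' @export
spectral_centroid <- function(profile) {
  stopifnot(inherits(profile, "band_energy_profile"))
  sum(profile$frequencies * profile$density)
}

#' Higher spectral moments of the band energy density
#'
#' Second to fourth central moments of p(f) about the spectral centroid:
#' variance (Hz^2), skewness (standardized 3rd moment) and kurtosis
#' (standardized 4th moment, Pearson convention, i.e. 3 for a Gaussian
#' shape, not excess). A degenerate single-bin profile has variance 0 and
#' skewness/kurtosis defined as 0 so feature tables stay dense.
#'
#' @param profile a `band_energy_profile`.
#' @return list with `variance`, `skewness`, `kurtosis`.
#' @export
spectral_moments <- function(profile) {
  stopifnot(inherits(profile, "band_energy_profile"))
  f <- profile$frequencies
  p <- profile$density
  sc <- sum(f * p)
  v <- sum((f - sc)^2 * p)
  # degenerate: all mass on one bin (variance indistinguishable from 0)
  if (v <= (profile$bin_width * 1e-6)^2)
    return(list(variance = 0, skewness = 0, kurtosis = 0))
  m3 <- sum((f - sc)^3 * p)
  m4 <- sum((f - sc)^4 * p)
  list(variance = v, skewness = m3 / v^1.5, kurtosis = m4 / v^2)
}

#' Extract all band timbre parameters from a waveform
#'
#' Convenience chain: [compute_spectrum()] -> [band_energy_profile()] ->
#' FHE, PHE, SC and spectral moments. Deterministic for fixed input and
#' parameters, and invariant under global amplitude scaling (the density
#' normalization cancels loudness).
#'
#' @param samples mono waveform (or multichannel matrix, mean-downmixed).
#' @param sample_rate Hz; must be at least twice the band's upper edge.
#' @param voice_type voice type name or `voice_band`.
#' @param window_length,overlap,nfft spectral estimation settings, see
#'   [compute_spectrum()].
#' @return object of class `timbre_features`: `fhe` (Hz), `phe` (%),
#'   `sc` (Hz), `spectral_variance` (Hz^2), `spectral_skewness`,
#'   `spectral_kurtosis`, `band`, `band_energy`.
#' @examples
#' fs <- 44100
#' t <- seq(0, 0.5, by = 1 / fs)
#' x <- sin(2 * pi * 2500 * t) + 0.5 * sin(2 * pi * 3100 * t)
#' extract_timbre(x, fs, "tenor")
#' @export
extract_timbre <- function(samples, sample_rate, voice_type,
                           window_length = 4096L, overlap = 0.5,
                           nfft = window_length) {
  band <- as_voice_band(voice_type)
  check_band_nyquist(band, sample_rate)
  sp <- compute_spectrum(samples, sample_rate, window_length = window_length,
                         overlap = overlap, nfft = nfft)
  prof <- band_energy_profile(sp, band)
  fhe <- frequency_of_half_energy(prof)
  mom <- spectral_moments(prof)
  structure(list(
    fhe = fhe,
    phe = position_of_half_energy(fhe, band),
    sc = spectral_centroid(prof),
    spectral_variance = mom$variance,
    spectral_skewness = mom$skewness,
    spectral_kurtosis = mom$kurtosis,
    band = band,
    band_energy = prof$band_energy
  ), class = "timbre_features")
}

#' @export
print.timbre_features <- function(x, ...) {
  cat(sprintf(
    "<timbre_features> %s band [%g, %g] Hz\n  FHE %.1f Hz | PHE %.2f %% | SC %.1f Hz\n  variance %.0f Hz^2 | skewness %.3f | kurtosis %.3f\n",
    x$band$voice_type, x$band$b1, x$band$b2, x$fhe, x$phe, x$sc,
    x$spectral_variance, x$spectral_skewness, x$spectral_kurtosis))
  invisible(x)
}
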