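# shared fixtures and independent oracles used across test files

# build a power_spectrum directly from magnitudes (bypasses the DSP path)
make_spectrum <- function(magnitudes, bin_width = 10, f_start = 0,
                          sample_rate = 44100) {
  n <- length(magnitudes)
  structure(list(
    frequencies = f_start + (seq_len(n) - 1L) * bin_width,
    magnitudes = magnitudes,
    bin_width = bin_width,
    meta = list(sample_rate = sample_rate, window = "none",
                nfft = n, n_frames = 1L, window_length = n)
  ), class = "power_spectrum")
}

# brute-force reference for the band energy parameters: explicit loops,
# same band-membership and interpolation conventions as the package
oracle_band <- function(spectrum, band) {
  f <- spectrum$frequencies
  bw <- spectrum$bin_width
  idx <- integer(0)
  for (i in seq_along(f)) {
    if ((f[i] >= band$b1 && f[i] < band$b2) ||
        (f[i] - bw / 2 <= band$b2 && band$b2 < f[i] + bw / 2))
      idx <- c(idx, i)
  }
  s2 <- spectrum$magnitudes[idx]^2
  total <- 0
  for (v in s2) total <- total + v
  dens <- s2 / total
  cum <- numeric(length(dens))
  acc <- 0
  for (i in seq_along(dens)) {
    acc <- acc + dens[i]
    cum[i] <- acc
  }
  fb <- f[idx]
  # FHE: linear interpolation between straddling bins
  k <- NA_integer_
  for (i in seq_along(cum)) if (cum[i] >= 0.5) { k <- i; break }
  fhe <- if (k == 1L) fb[1L] else
    fb[k - 1L] + (0.5 - cum[k - 1L]) / (cum[k] - cum[k - 1L]) *
      (fb[k] - fb[k - 1L])
  sc <- 0
  for (i in seq_along(dens)) sc <- sc + fb[i] * dens[i]
  v <- 0; m3 <- 0; m4 <- 0
  for (i in seq_along(dens)) {
    d <- fb[i] - sc
    v <- v + d^2 * dens[i]
    m3 <- m3 + d^3 * dens[i]
    m4 <- m4 + d^4 * dens[i]
  }
  list(frequencies = fb, density = dens, cumulative = cum, fhe = fhe,
       sc = sc, variance = v,
       skewness = if (v > 0) m3 / v^1.5 else 0,
       kurtosis = if (v > 0) m4 / v^2 else 0)
}

# short harmonic test tone without the synthesizer (independent path)
make_tone <- function(freqs, amps, duration = 1, fs = 44100,
                      phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_along(freqs))
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phase)
  x
}
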