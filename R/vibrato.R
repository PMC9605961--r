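#' Track one harmonic of a sung tone over time
#'
#' Frame-wise peak tracking of partial `harmonic_index * f0` through a
#' short-window STFT. Each frame searches for the strongest spectral peak
#' within a quarter-tone of the previous frame's estimate (seeded at
#' `harmonic_index * f0_hint`), so slow vibrato excursions well beyond a
#' quarter tone are followed without losing lock. Peak frequencies are
#' refined by parabolic interpolation of the log-magnitude on a zero-padded
#' transform, giving sub-bin precision.
#'
#' @param samples mono waveform (multichannel is mean-downmixed).
#' @param sample_rate Hz.
#' @param f0_hint approximate fundamental, Hz; must lie in \[50, 1500\].
#' @param harmonic_index which partial to track (1 = fundamental).
#' @param window_length STFT window (Hann), short enough that vibrato does
#'   not smear within a frame; default 1024 samples (~23 ms at 44.1 kHz).
#' @param hop hop size in samples; default `window_length / 4`.
#' @param nfft zero-padded transform length for peak interpolation.
#' @return object of class `harmonic_contour` with `times` (s),
#'   `frequencies` (Hz), `amplitudes` (linear), `harmonic_index`.
#' @export
track_harmonic <- function(samples, sample_rate, f0_hint, harmonic_index = 1L,
                           window_length = 1024L, hop = window_length %/% 4L,
                           nfft = 8192L) {
  samples <- downmix(samples)
  if (f0_hint < 50 || f0_hint > 1500)
    stop("f0_hint must be within [50, 1500] Hz", call. = FALSE)
  target <- harmonic_index * f0_hint
  if (target >= sample_rate / 2)
    stop("harmonic exceeds Nyquist", call. = FALSE)
  n <- length(samples)
  if (n < window_length) stop("segment too short", call. = FALSE)
  win <- hann_window(window_length)
  starts <- seq.int(1L, n - window_length + 1L, by = hop)
  bw <- sample_rate / nfft
  qt <- 2^(1 / 24)                      # quarter-tone search half-width
  nbins <- nfft %/% 2L + 1L
  freqs <- numeric(length(starts))
  amps <- numeric(length(starts))
  ok <- logical(length(starts))
  center <- target
  for (j in seq_along(starts)) {
    s <- starts[j]
    frame <- samples[s:(s + window_length - 1L)] * win
    X <- Mod(stats::fft(c(frame, numeric(nfft - window_length)))[seq_len(nbins)])
    lo <- max(2L, floor(center / qt / bw) + 1L)
    hi <- min(nbins - 1L, ceiling(center * qt / bw) + 1L)
    if (lo >= hi) break
    seg <- X[lo:hi]
    k <- lo + which.max(seg) - 1L
    # require a genuine local peak with energy above the frame noise floor
    if (X[k] <= 10 * stats::median(X) || X[k] < X[k - 1L] || X[k] < X[k + 1L]) {
      ok[j] <- FALSE
      next
    }
    pk <- parabolic_peak(log(X[(k - 1L):(k + 1L)] + 1e-300))
    freqs[j] <- (k - 1L + pk$offset) * bw
    amps[j] <- X[k]
    ok[j] <- TRUE
    center <- freqs[j]
  }
  if (mean(ok) < 0.5) stop("harmonic lost", call. = FALSE)
  keep <- which(ok)
  structure(list(
    times = (starts[keep] - 1L + window_length / 2) / sample_rate,
    frequencies = freqs[keep],
    amplitudes = amps[keep],
    harmonic_index = as.integer(harmonic_index),
    frame_rate = sample_rate / hop
  ), class = "harmonic_contour")
}

# zero-phase band-pass via FFT masking with raised-cosine transitions;
# exact linear phase and numerically stable at any band placement
fft_bandpass <- function(x, fs, lo, hi, transition) {
  n <- length(x)
  fs <- as.numeric(fs)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * (fs / n)
  f <- pmin(f, fs - f)                      # fold to two-sided magnitude
  ramp <- function(d) 0.5 * (1 + cos(pi * pmin(pmax(d, 0), 1)))
  gain <- ifelse(f >= lo & f <= hi, 1,
                 ifelse(f < lo, ramp((lo - f) / transition),
                        ramp((f - hi) / transition)))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# vertex offset (in bins, in [-0.5, 0.5]) of a parabola through 3 points
parabolic_peak <- function(y3) {
  d <- y3[1] - 2 * y3[2] + y3[3]
  off <- if (abs(d) < 1e-12) 0 else 0.5 * (y3[1] - y3[3]) / d
  list(offset = max(-0.5, min(0.5, off)))
}

#' Vibrato rate and extent from a harmonic contour
#'
#' The contour is converted to cents relative to its median
#' (`1200 * log2(f / f_ref)`), linearly detrended, and its modulation
#' spectrum searched for the dominant peak inside the physiological vibrato
#' range 3--9 Hz; the peak frequency (parabolically interpolated) is the
#' vibrato rate VR. The extent VE is the peak-to-peak excursion in cents of
#' the vibrato-rate component, obtained by least-squares sinusoidal fit at
#' VR (twice the fitted amplitude); the fit averages out frame-wise
#' tracking noise that would bias a raw max-minus-min swing upward.
#' Vibrato is flagged absent when no modulation peak stands above the noise
#' floor of the 3--9 Hz band or the swing is negligible (< 5 cents).
#'
#' @param contour a `harmonic_contour` of at least 1 s.
#' @param rate_range search band for the modulation peak, Hz.
#' @return list: `present` (logical), `vr` (Hz), `ve` (cents, peak-to-peak);
#'   `vr`/`ve` are `NA` when vibrato is absent.
#' @export
vibrato_features <- function(contour, rate_range = c(3, 9)) {
  stopifnot(inherits(contour, "harmonic_contour"))
  t <- contour$times
  dur <- t[length(t)] - t[1]
  if (dur < 1) stop("contour shorter than 1 s", call. = FALSE)
  # resample to a uniform grid in case frames were dropped
  fr <- contour$frame_rate
  tu <- seq(t[1], t[length(t)], by = 1 / fr)
  f <- stats::approx(t, contour$frequencies, xout = tu)$y
  cents <- 1200 * log2(f / stats::median(f))
  x <- stats::residuals(stats::lm(cents ~ tu))
  n <- length(x)
  nfft <- 2^ceiling(log2(n * 16))
  X <- Mod(stats::fft(c(x * hann_window(n), numeric(nfft - n))))
  fm <- (seq_len(nfft %/% 2L) - 1L) * fr / nfft
  band <- which(fm >= rate_range[1] & fm <= rate_range[2])
  if (length(band) < 3L) return(list(present = FALSE, vr = NA_real_,
                                     ve = NA_real_))
  k <- band[which.max(X[band])]
  # peak must dominate the band: otherwise no periodic modulation
  if (X[k] < 6 * stats::median(X[band]) || stats::sd(x) < 2)
    return(list(present = FALSE, vr = NA_real_, ve = NA_real_))
  pk <- parabolic_peak(log(X[(k - 1L):(k + 1L)] + 1e-300))
  vr <- (k - 1L + pk$offset) * fr / nfft
  # peak-to-peak extent of the vibrato-rate component, by least-squares
  # sinusoidal fit at vr (robust to frame-wise tracking noise, which would
  # bias a raw max-minus-min swing upward)
  fit <- stats::lm(x ~ cos(2 * pi * vr * tu) + sin(2 * pi * vr * tu))
  ve <- 2 * sqrt(sum(stats::coef(fit)[2:3]^2))
  if (ve < 5) return(list(present = FALSE, vr = NA_real_, ve = NA_real_))
  list(present = TRUE, vr = vr, ve = ve)
}

#' Jitter and shimmer of a sustained tone
#'
#' Local (first-order difference) perturbation measures. Cycles are
#' delimited by upward zero crossings of the band-limited fundamental
#' (zero-phase FFT-domain band-pass, 0.4--1.6 f0 with raised-cosine
#' transitions: wide enough to retain the cycle-rate period-noise
#' sidebands that a narrow filter would smooth away, and numerically
#' clean at any band placement, which an IIR filter at such small
#' normalized frequencies is not). Crossing instants are refined to
#' sub-sample precision by solving a local cubic fit, and per-cycle
#' amplitudes are the RMS of the waveform integrated between the
#' fractional crossing times, which scales one-to-one with any per-cycle
#' gain. Because amplitude steps would bend the filtered fundamental near
#' its crossings and leak into the timing, the waveform is
#' amplitude-demodulated by the per-cycle RMS envelope and the cycles
#' re-timed, twice (the first-pass marks are themselves biased by the
#' amplitude perturbation). Jitter is `mean(|T_i - T_{i-1}|) / mean(T) *
#' 100` over the final cycle lengths; shimmer is the same statistic over
#' the per-cycle amplitudes. Both are scale invariant in amplitude and
#' time units.
#'
#' @param samples mono waveform.
#' @param sample_rate Hz.
#' @param f0_hint approximate fundamental, Hz.
#' @return list with `jitter` (%), `shimmer` (%), `n_cycles`.
#' @export
perturbation <- function(samples, sample_rate, f0_hint) {
  samples <- downmix(samples)
  # pass 1: cycle marks on the band-limited fundamental
  marks <- fundamental_crossings(samples, sample_rate, f0_hint)
  if (length(marks$index) < 11L) stop("too few cycles", call. = FALSE)
  i <- marks$index

  # per-cycle amplitude: RMS of the raw waveform over each cycle (scales
  # one-to-one with any per-cycle gain); integrated between the
  # fractional crossing times so that every cycle covers exactly one
  # period of phase, otherwise the 200-vs-201-sample alternation of a
  # non-integer cycle length leaves a spurious amplitude ripple
  # amplitude is measured on a copy band-limited below a quarter of the
  # sample rate: squaring doubles the top frequency, and content pushed
  # past Nyquist would alias and beat against the sample grid as a
  # spurious ~0.1% amplitude ripple
  xa <- fft_bandpass(samples, sample_rate, 0, 0.2 * sample_rate,
                     transition = 0.025 * sample_rate)
  # integrate xa^2 treating xa as piecewise linear (exact for the
  # quadratic growth of x^2 away from a crossing, where a rectangle rule
  # leaves a grid-phase-dependent ripple)
  nx <- length(xa)
  cell <- (xa[-nx]^2 + xa[-nx] * xa[-1] + xa[-1]^2) / 3
  cum <- c(0, cumsum(cell))
  energy_to <- function(t) {           # integral of xa^2 from 0 to t (s)
    u <- t * sample_rate
    k <- pmin(floor(u), nx - 2L)
    th <- u - k
    a <- xa[k + 1L]; b <- xa[k + 2L]
    cum[k + 1L] + a^2 * th + a * (b - a) * th^2 + (b - a)^2 * th^3 / 3
  }
  # passes 2-3: demodulate the per-cycle amplitude, re-time the cycles,
  # and repeat once (amplitude perturbation biases the first-pass marks
  # by a few samples, which would misplace the envelope steps)
  cycle_amps <- function(mk) {
    tc <- mk$time
    vapply(seq_len(length(tc) - 1L), function(j) {
      sqrt((energy_to(tc[j + 1L]) - energy_to(tc[j])) /
           ((tc[j + 1L] - tc[j]) * sample_rate))
    }, numeric(1))
  }
  amps <- cycle_amps(marks)
  for (pass in 1:2) {
    i <- marks$index
    env <- rep(1, length(samples))
    env[seq_len(i[1] - 1L)] <- amps[1]
    for (j in seq_len(length(i) - 1L)) env[i[j]:(i[j + 1L] - 1L)] <- amps[j]
    env[i[length(i)]:length(samples)] <- amps[length(amps)]
    norm <- samples / pmax(env, max(env) * 1e-6)
    marks <- fundamental_crossings(norm, sample_rate, f0_hint)
    if (length(marks$index) < 11L) stop("too few cycles", call. = FALSE)
    amps <- cycle_amps(marks)
  }
  shimmer <- mean(abs(diff(amps))) / mean(amps) * 100
  periods <- diff(marks$time)
  periods <- periods[periods > 0.5 / f0_hint & periods < 2 / f0_hint]
  if (length(periods) < 10L) stop("too few cycles", call. = FALSE)
  jitter <- mean(abs(diff(periods))) / mean(periods) * 100

  list(jitter = jitter, shimmer = shimmer, n_cycles = length(periods))
}

# upward zero crossings of the FFT-band-limited fundamental, cubic-refined
# to sub-sample precision; returns integer indices and fractional times
fundamental_crossings <- function(x, fs, f0) {
  fund <- fft_bandpass(x, fs, 0.4 * f0, min(1.6 * f0, 0.95 * fs / 2),
                       transition = 0.1 * f0)
  n <- length(fund)
  i <- which(fund[-n] < 0 & fund[-1] >= 0)
  edge <- 2 * fs / f0
  i <- i[i >= max(2, edge) & i <= n - max(2, edge)]
  if (length(i) < 3L) return(list(index = integer(0), time = numeric(0)))
  # drop spurious marks (octave errors from residual ripple)
  gaps <- diff(i)
  ok <- gaps > 0.5 * fs / f0 & gaps < 2 * fs / f0
  i <- i[c(TRUE, ok)]
  vander_inv <- solve(cbind(1, c(-1, 0, 1, 2), c(-1, 0, 1, 2)^2,
                            c(-1, 0, 1, 2)^3))
  frac <- vapply(i, function(k) {
    cf <- vander_inv %*% fund[(k - 1L):(k + 2L)]
    fcub <- function(u) cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
    if (fcub(1) <= 0 || fcub(0) >= 0)       # fall back to linear
      return(-fund[k] / (fund[k + 1L] - fund[k]))
    stats::uniroot(fcub, c(0, 1), tol = 1e-12)$root
  }, numeric(1))
  list(index = i, time = (i - 1 + frac) / fs)
}

#' Formant band strength and extent
#'
#' Summarizes how much of the overall spectral energy sits in the singer's
#' formant band and where the band's energy concentration begins and ends.
#' Strength is `10 * log10(band energy / total energy up to 8 kHz)` in dB
#' (0 dB when all energy is inside the band, negative otherwise). Start and
#' stop are the lowest and highest band frequencies at which the smoothed
#' energy density exceeds a fraction `theta` of its maximum; decreasing
#' `theta` widens the bracket monotonically.
#'
#' @param spectrum a `power_spectrum`.
#' @param band a `voice_band` or voice type name.
#' @param theta density threshold as a fraction of the smoothed maximum.
#' @param smooth_hz moving-average smoothing width for the density, Hz.
#' @return list with `strength` (dB), `start` (Hz), `stop` (Hz).
#' @export
formant_band_features <- function(spectrum, band, theta = 0.25,
                                  smooth_hz = 50) {
  band <- as_voice_band(band)
  prof <- band_energy_profile(spectrum, band)
  f <- spectrum$frequencies
  total_idx <- which(f <= 8000)
  total <- sum(spectrum$magnitudes[total_idx]^2)
  if (total <= 0) stop("no energy in spectrum", call. = FALSE)
  strength <- 10 * log10(prof$band_energy / total)
  w <- max(1L, round(smooth_hz / prof$bin_width))
  if (w %% 2L == 0L) w <- w + 1L
  dens <- stats::filter(prof$density, rep(1 / w, w), sides = 2)
  dens[is.na(dens)] <- 0
  above <- which(dens >= theta * max(dens))
  list(strength = strength,
       start = prof$frequencies[min(above)],
       stop = prof$frequencies[max(above)])
}
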