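test_that("spectrum estimation localizes tones and rejects bad input", {
  fs <- 44100
  x <- make_tone(3000, 1, duration = 2, fs = fs)
  sp <- compute_spectrum(x, fs)
  expect_lt(abs(sp$frequencies[which.max(sp$magnitudes)] - 3000),
            sp$bin_width)
  expect_true(all(sp$magnitudes >= 0))
  expect_lt(max(abs(diff(sp$frequencies) - sp$bin_width)), 1e-9)

  silence <- compute_spectrum(numeric(8192), fs)
  expect_true(all(silence$magnitudes == 0))

  expect_error(compute_spectrum(numeric(100), fs), "segment too short")
  expect_error(extract_timbre(x, 6000, "tenor"), "band exceeds Nyquist")
})

test_that("white-noise band energy fraction is stable across window lengths", {
  fs <- 44100
  ratios <- sapply(1:20, function(seed) {
    set.seed(seed)
    x <- rnorm(fs)
    frac <- sapply(c(2048L, 4096L), function(wl) {
      sp <- compute_spectrum(x, fs, window_length = wl, nfft = wl)
      prof <- band_energy_profile(sp, "tenor")
      prof$band_energy / sum(sp$magnitudes^2)
    })
    frac[1] / frac[2]
  })
  expect_true(all(abs(ratios - 1) < 0.10))
})

test_that("band energy profile matches its definition and flags empty bands", {
  band <- voice_band("tenor")

  # flat spectrum: uniform density, linear cumulative
  sp <- make_spectrum(rep(2, 500), bin_width = 10)
  prof <- band_energy_profile(sp, band)
  nb <- length(prof$density)
  expect_equal(prof$density, rep(1 / nb, nb))
  expect_equal(prof$cumulative, seq_len(nb) / nb)

  # single nonzero bin at 2500 Hz
  mags <- numeric(500)
  mags[251] <- 3          # f = 2500 at bin_width 10
  prof1 <- band_energy_profile(make_spectrum(mags, 10), band)
  expect_equal(sum(prof1$density), 1)
  expect_equal(prof1$density[prof1$frequencies == 2500], 1)
  expect_true(all(prof1$cumulative[prof1$frequencies < 2500] == 0))
  expect_true(all(prof1$cumulative[prof1$frequencies >= 2500] == 1))

  expect_error(band_energy_profile(make_spectrum(numeric(500), 10), band),
               "no energy in band")
})

test_that("random spectra reproduce the brute-force prefix-sum oracle", {
  # note: base R's sum()/cumsum() accumulate in extended precision, the
  # oracle's explicit loops in double, so agreement is checked at 1e-12
  band <- voice_band("tenor")
  set.seed(42)
  for (i in 1:10) {
    sp <- make_spectrum(runif(450, 0, 5), bin_width = 10.77)
    prof <- band_energy_profile(sp, band)
    orc <- oracle_band(sp, band)
    expect_identical(prof$frequencies, orc$frequencies)
    expect_equal(prof$cumulative, orc$cumulative, tolerance = 1e-12)
    expect_equal(prof$density, orc$density, tolerance = 1e-12)
  }
})

test_that("FHE follows the frozen interpolation rule", {
  band <- voice_band("tenor")

  # flat spectrum: half energy at the band midpoint
  prof <- band_energy_profile(make_spectrum(rep(1, 500), 10), band)
  expect_lt(abs(frequency_of_half_energy(prof) - 2800), 10)

  # all energy in one bin
  mags <- numeric(500); mags[251] <- 1
  prof1 <- band_energy_profile(make_spectrum(mags, 10), band)
  expect_lt(abs(frequency_of_half_energy(prof1) - 2500), 10)

  # two equal bins at 2400 and 3000: first bin reaching P >= 0.5 wins
  mags2 <- numeric(500); mags2[c(241, 301)] <- 1
  prof2 <- band_energy_profile(make_spectrum(mags2, 10), band)
  fhe <- frequency_of_half_energy(prof2)
  expect_gte(fhe, 2400 - 10)
  expect_lte(fhe, 2400)
})

test_that("PHE is the affine position of FHE inside the band", {
  band <- voice_band("custom", b1 = 2000, b2 = 3600)
  expect_equal(position_of_half_energy(2632, band), 39.5)
  expect_equal(position_of_half_energy(2000, band), 0)
  expect_equal(position_of_half_energy(3600, band), 100)
  expect_equal(position_of_half_energy(2800, band), 50)
  expect_error(position_of_half_energy(1900, band), "FHE outside band")
})

test_that("spectral centroid and moments match closed forms and the oracle", {
  band <- voice_band("tenor")

  mags <- numeric(500); mags[251] <- 4
  prof1 <- band_energy_profile(make_spectrum(mags, 10), band)
  expect_equal(spectral_centroid(prof1), 2500)
  mom1 <- spectral_moments(prof1)
  expect_equal(mom1, list(variance = 0, skewness = 0, kurtosis = 0))

  # symmetric triangular envelope centered at 3400 Hz in the soprano band
  sop <- voice_band("soprano")
  f <- (0:499) * 10
  tri <- pmax(0, 1 - abs(f - 3400) / 500)
  prof2 <- band_energy_profile(make_spectrum(tri, 10), sop)
  expect_lt(abs(spectral_centroid(prof2) - 3400), 10)
  expect_lt(abs(spectral_moments(prof2)$skewness), 1e-6)

  # uniform density over n bins with spacing d: variance d^2 (n^2 - 1) / 12
  prof3 <- band_energy_profile(make_spectrum(rep(1, 500), 10), band)
  n <- length(prof3$density)
  expect_equal(spectral_moments(prof3)$variance, 10^2 * (n^2 - 1) / 12,
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    sp <- make_spectrum(runif(450, 0, 2), 10.77)
    prof <- band_energy_profile(sp, band)
    orc <- oracle_band(sp, band)
    expect_equal(spectral_centroid(prof), orc$sc, tolerance = 1e-12)
    mom <- spectral_moments(prof)
    expect_equal(mom$variance, orc$variance, tolerance = 1e-12)
    expect_equal(mom$skewness, orc$skewness, tolerance = 1e-9)
    expect_equal(mom$kurtosis, orc$kurtosis, tolerance = 1e-9)
  }
})

test_that("timbre extraction is loudness invariant and translation covariant", {
  fs <- 44100
  # bump of partials around 3000 Hz inside the tenor band
  freqs <- seq(2200, 3400, by = 200)
  amps <- exp(-(freqs - 3000)^2 / (2 * 300^2))
  x <- make_tone(freqs, amps, duration = 1.5, fs = fs)
  tf <- extract_timbre(x, fs, "tenor")

  for (scale in c(1e-3, 0.1, 10, 1e3)) {
    tfs <- extract_timbre(scale * x, fs, "tenor")
    expect_equal(tfs$fhe, tf$fhe, tolerance = 1e-12)
    expect_equal(tfs$phe, tf$phe, tolerance = 1e-12)
    expect_equal(tfs$sc, tf$sc, tolerance = 1e-12)
    expect_equal(tfs$spectral_variance, tf$spectral_variance,
                 tolerance = 1e-9)
  }

  # shifting the whole envelope up by 200 Hz moves FHE and SC by 200 Hz
  x2 <- make_tone(freqs + 200, amps, duration = 1.5, fs = fs)
  tf2 <- extract_timbre(x2, fs, "tenor")
  bw <- 44100 / 4096
  expect_lt(abs((tf2$fhe - tf$fhe) - 200), 2 * bw)
  expect_lt(abs((tf2$sc - tf$sc) - 200), 2 * bw)

  # stored PHE is exactly the affine map of FHE
  expect_equal(tf$phe, (tf$fhe - 2000) / 1600 * 100, tolerance = 1e-12)
})

test_that("profile normalization and band containment hold on random spectra", {
  set.seed(11)
  bands <- list(voice_band("soprano"), voice_band("tenor"))
  for (i in 1:100) {
    band <- bands[[1 + i %% 2]]
    sp <- make_spectrum(runif(460, 0, 3), 10.77)
    prof <- band_energy_profile(sp, band)
    expect_lt(abs(sum(prof$density) - 1), 1e-9)
    expect_lt(abs(prof$cumulative[length(prof$cumulative)] - 1), 1e-9)
    expect_true(all(diff(prof$cumulative) >= -1e-15))
    fhe <- frequency_of_half_energy(prof)
    sc <- spectral_centroid(prof)
    expect_gte(fhe, band$b1); expect_lte(fhe, band$b2)
    expect_gte(sc, band$b1);  expect_lte(sc, band$b2)
    orc <- oracle_band(sp, band)
    expect_equal(fhe, orc$fhe, tolerance = 1e-9)
    expect_equal(sc, orc$sc, tolerance = 1e-9)
  }
})

test_that("moving energy above the half-energy point raises FHE", {
  band <- voice_band("tenor")
  set.seed(13)
  mags <- runif(450, 0.5, 2)
  sp <- make_spectrum(mags, 10.77)
  prof <- band_energy_profile(sp, band)
  fhe0 <- frequency_of_half_energy(prof)
  # transfer energy from bins below FHE to bins above it
  f <- sp$frequencies
  lo <- which(f >= band$b1 & f < fhe0)
  hi <- which(f > fhe0 & f <= band$b2)
  mags2 <- mags
  mags2[lo] <- mags2[lo] * 0.5
  mags2[hi] <- sqrt(mags2[hi]^2 + sum(mags[lo]^2 - mags2[lo]^2) / length(hi))
  fhe1 <- frequency_of_half_energy(band_energy_profile(
    make_spectrum(mags2, 10.77), band))
  expect_gt(fhe1, fhe0)
})
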