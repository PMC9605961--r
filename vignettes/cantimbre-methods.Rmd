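---
title: "Quantifying singing-voice timbre: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying singing-voice timbre: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cantimbre)
```

## The problem

Voice timbre — the color of a voice independent of pitch, loudness and
vowel — is carried largely by the 2–4 kHz region where the 3rd–5th
formants of trained singers cluster into the *singer's formant*. Voices
whose energy concentration sits higher in this region are heard as
brighter and assigned to higher voice types; within a voice type, lyric
voices tend to sit higher than dramatic ones. `cantimbre` turns this
perceptual judgement into band-limited spectral statistics computable from
a single sustained sung tone, and provides the surrounding workflow:
ground-truthed synthesis, cohort statistics, and a random-forest
lyric-vs-dramatic ("Fach" or voice-structure) classifier.

## Band energy parameters

All timbre parameters are computed on a fixed analysis band $[B_1, B_2]$
per voice type — soprano 2300–4500 Hz; tenor, baritone and bass
2000–3600 Hz — chosen above the vowel formants so that deliberate vowel
coloring does not move them, and shared within each gender so groups are
comparable.

Given a magnitude spectrum $S(f)$, the band energy density and cumulative
distribution are

$$p(f) = \frac{S^2(f)}{\sum_{B_1}^{B_2} S^2(i)}, \qquad
  P(f) = \sum_{i=B_1}^{f} p(i).$$

* **FHE** (frequency of half energy): the frequency where $P(f) = 0.5$,
  in Hz. The headline parameter; easy to visualise as the point where the
  running energy curve crosses its midline.
* **PHE** (position of half energy):
  $(f_{FHE} - B_1)/(B_2 - B_1)\cdot 100$, the relative band position in
  percent. Affinely equivalent to FHE within one band, but with a larger
  SD-to-mean ratio, which classifiers prefer.
* **SC** (spectral centroid): $\sum f\, p(f)$, the energetic center of
  the band, in Hz.
* Higher moments: spectral variance $\sum (f - SC)^2 p(f)$ (Hz²),
  skewness and kurtosis (standardized 3rd/4th central moments). Kurtosis
  uses the Pearson (non-excess) convention: a Gaussian-shaped density
  scores 3, not 0.

Because $p(f)$ is normalized, every parameter is invariant under global
amplitude scaling: loudness does not enter.

## Spectral estimation

The magnitude spectrum is a Welch-style long-term average — the standard
estimator in singer's-formant work: Hann-windowed frames of 4096 samples
at 50% overlap, per-frame squared FFT magnitudes averaged over the whole
analysis interval, square root stored as $S(f)$. At 44.1 kHz this gives
≈10.77 Hz bins, two orders of magnitude finer than the 1600–2200 Hz wide
bands. Numerical conventions, frozen so results are reproducible to the
bit:

* Band membership: bins with center in $[B_1, B_2)$ plus the bin
  containing $B_2$, so $P$ at the last band bin is exactly 1.
* The $P = 0.5$ crossing is solved by linear interpolation between the
  straddling bins (if the first band bin already holds half the energy,
  its center is returned). This removes bin-width quantization from FHE.
* A single-bin (zero-variance) profile has skewness and kurtosis defined
  as 0, keeping feature tables dense.
* Input below twice the band's upper edge is rejected
  (`band exceeds Nyquist`) rather than resampled silently; multichannel
  audio is mean-downmixed.

## Vibrato and perturbation co-features

The classifier uses vibrato and perturbation features alongside timbre.
Their published definitions are not fully specified, so this package
freezes conventional, auditable reimplementations (they are *not* claimed
to replicate any particular prior implementation):

* **Harmonic tracking**: short-window STFT (1024 samples ≈ 23 ms, hop
  256) peak tracking within a quarter-tone of the previous frame's
  estimate, parabolic interpolation on a zero-padded transform for
  sub-bin precision. The adaptive center lets the tracker follow
  excursions far beyond a quarter-tone without losing lock.
* **VR** (vibrato rate): dominant modulation-spectrum peak of the
  detrended cents contour inside the physiological 3–9 Hz range,
  parabolically interpolated.
* **VE** (vibrato extent): peak-to-peak, in cents
  ($1200\log_2 f/f_{ref}$, $f_{ref}$ the contour median). Estimated as
  twice the amplitude of a least-squares sinusoid fitted at VR: the fit
  averages out frame-wise tracking noise, which would bias a raw
  max-minus-min swing upward by several cents at realistic SNR. For
  strongly non-sinusoidal vibrato this reports the fundamental component
  of the modulation only.
* Vibrato is flagged absent when no 3–9 Hz peak stands clear of the band
  noise floor or the fitted swing is below 5 cents.
* **Jitter/shimmer**: local (first-order difference) variants,
  `mean |x_i − x_{i−1}| / mean x · 100` over cycle lengths and per-cycle
  amplitudes. Cycle marks come from upward zero crossings of the
  band-limited fundamental, cubic-refined to sub-sample precision; the
  band-limiting is a zero-phase FFT mask (0.4–1.6 f₀, raised-cosine
  transitions) — wide enough to keep the cycle-rate period-noise
  sidebands that a narrow filter would smooth away, and numerically
  clean where an IIR filter at ~0.003 normalized frequency is fragile.
  Per-cycle amplitudes are RMS values integrated between the fractional
  crossing times (on a copy band-limited below fs/4, since squaring
  would otherwise alias the top octave into a grid-phase amplitude
  ripple). Amplitude steps bend the filtered fundamental near its
  crossings, so before timing is read off, the waveform is
  amplitude-demodulated by the per-cycle RMS envelope and the cycles
  re-timed, iterating once; this keeps shimmer from leaking into jitter
  (residual crosstalk ≲0.1 percentage points at 3% shimmer).
* **Formant band descriptors**: strength
  $10\log_{10}(\text{band energy}/\text{0–8 kHz energy})$ in dB; start
  and stop are the outermost band frequencies where the smoothed density
  exceeds a fraction $\theta$ (default 0.25, exposed) of its maximum.

## The synthetic voice generator

Real recordings of professional singers cannot be packaged, so every
claim is exercised on synthetic tones with analytic ground truth.
`voice_spec()`/`synthesize()` build an additive harmonic tone: partial
$k$ carries a fixed gain from a spectral envelope (Gaussian dB bumps for
vowel formants and the singer's-formant cluster on a −6 dB/octave source
tilt) evaluated at $k f_0$; all partials share a common FM vibrato
(physiologically, vibrato is an F0 modulation); jitter perturbs each
fundamental cycle's period and shimmer each cycle's gain (applied at
waveform zeros, so no clicks); white noise is added at a chosen SNR.
Defaults emulate a typical sustained operatic tone: $f_0$ 220 Hz, 3 s,
vibrato 5.5 Hz / 100 cents peak-to-peak, jitter 0.3%, shimmer 2%,
30 dB SNR.

Ground truth is computed from the *designed line spectrum* ($k f_0$ and
envelope gains), independently of the Welch/FFT analysis path, because a
harmonic tone carries band energy only at its partials — the centroid of
the continuous envelope is not the centroid of the tone. A dense 1 Hz
grid of the continuous envelope is attached for reference. Recovery
tests run the timbre grid with vibrato off (FM smears each partial by
±extent/2 cents, which is a property of the signal, not an analysis
error) and verify FHE/SC within 2 analysis bins of the line-spectrum
truth across formant-cluster positions spanning each band.

What the generator does *not* emulate: vocal-tract interaction,
inter-harmonic noise shaping, onset/offset dynamics, room acoustics, or
per-harmonic independent amplitude modulation. Passing recovery tests
therefore demonstrates correctness of the measurement chain on idealized
tones, not performance on stage recordings.

`sample_population()` draws labeled two-class feature tables from
per-feature Gaussian (mean, SD) parameters — the natural emulation of a
cohort reported as means and SDs whose distributions pass a
skewness-in-(−1,1) screen — independently by default, or with a supplied
correlation matrix (via its Cholesky factor) to mimic the strong observed
PHE–SC dependence. Default parameters come from the bundled cohort
reference table (PHE, SC) and vibrato reference constants (VR, VE). The
vibrato constants for five voice groups are back-derived from published
95% reference ranges of group means; groups without published values
(dramatic baritone, basses) carry physiologically plausible stand-ins and
are marked `assumed` in the data file. Jitter/shimmer class parameters
are weakly separated values typical of trained voices.

## Cohort statistics

`describe_groups()` reports sample means and n−1 SDs.
`reference_interval()` implements two dialects, because cohort tables in
this field are ambiguous: the literal population reference range
(mean ± 1.96·SD) and the 95% confidence interval of the mean
(mean ± 1.96·SD/√n). The bundled cohort table's printed bounds are only
consistent with the latter, so `ci_of_mean` is the default for
reconstruction; both are exposed and named rather than resolved
silently. An integer rounding mode matches whole-Hz printed tables; a
handful of printed sub-group bounds remain 1 Hz off under any rounding
rule, consistent with the source computing from unrounded means.

The t-test defaults to the Student pooled-variance form (the Welch
variant is a flag), skewness uses the adjusted Fisher–Pearson estimator
(`e1071`, type 2) with a (−1, 1) gate before parametric comparisons, and
`select_energy_features()` drops FHE in favour of PHE and SC, verifying
numerically on the supplied table that PHE's SD/mean ratio exceeds FHE's
(an affine identity: the mapping shrinks the mean while scaling the SD)
and that PHE correlates less with SC — applied per voice type when a
table mixes bands. No multiple-testing correction is applied, matching
standard practice for these descriptive cohort tables.

## Voice-structure classification

`train_fach_forest()` wraps a `ranger` probability forest: 500 trees,
√d features per split, class-balanced bootstrap (each tree draws the
minority-class count from both classes), single-threaded and
seed-deterministic. Importance is the forest's mean impurity decrease
per feature, normalized to sum to 1 — the information-gain-style
importance of tree ensembles. (The installed forests split on Gini
impurity; Gini and Shannon-entropy gain are monotonically near-equivalent
binary impurity measures and rank features identically in practice, so
the Gini decrease is reported as the information-gain importance.)
Evaluation is stratified 5-fold cross-validation of the balanced error
rate (mean of the two class-conditional error rates), the right measure
for imbalanced lyric/dramatic cohorts.

`attribution_summary()` computes *exact interventional Shapley values*
of P(dramatic): all $2^d$ feature coalitions are evaluated against a
background sample (hybrids take coalition features from the explained
sample, the rest from background rows) and Shapley-weighted. Local
accuracy — attributions summing to prediction minus base value — holds
by construction on every sample, and for a binary model the attributions
toward the lyric class are exact negatives, so only the dramatic side is
materialized. Cost is $2^d \cdot n_{background}$ model evaluations per
sample; the implementation refuses d > 12 and caps the background at 25
rows (deterministically subsampled), which is ample for the compact
feature sets used here.

On synthetic cohort-parameter baritone populations the cross-validated
BER comes out around 13–16%. Published real-audio error rates are **not**
reproduction targets: the underlying recordings cannot be packaged, and
synthetic Gaussian populations are an easier problem than stage
recordings. The synthetic BER is reported for context only.

A subtlety worth naming: with the cohort parameters, SC's designed
standardized separation (≈1.46) leads PHE's (≈1.28) only modestly, so a
finite sample sometimes *realizes* the opposite order — in which case
PHE deservedly tops the importance ranking. The importance tests
therefore check that the feature realizing the widest separation (SC in
the large majority of draws) ranks first whenever its lead is decisive,
and the acceptance workflow uses populations where SC's lead is designed
to be unambiguous.

## Problem sizes and determinism

All randomness flows through explicit integer seeds: synthesis noise
through `voice_spec(seed=)`, sampling through `sample_population(seed=)`,
forests through `train_fach_forest(seed=)` with one `ranger` thread. The
shipped checks use tone durations of 1.5–3 s, recovery grids of 5 + 4
formant positions and a 3 × 3 vibrato grid, populations of 60–400 rows
per class and forests of 200–500 trees — sizes chosen so the full suite
exercises every claim in a few minutes on one core while keeping
Monte-Carlo margins comfortable.

## Known limitations

* The WAV layer reads integer PCM (8/16/24/32-bit) and IEEE float; no
  compressed formats.
* The vibrato extractor assumes a quasi-stationary sustained tone; it is
  not an onset-tolerant running-speech tracker.
* Jitter/shimmer here are research-grade signal statistics on sustained
  synthetic-like tones, not a clinically validated perturbation analysis.
* Formant start/stop depend on the smoothing width and θ; both are
  exposed and should be reported with any results.
* The classifier workflow models one voice type at a time (the bundled
  cohort constants show basses barely separate by structure at all —
  an 8 Hz mean FHE difference — so a bass classifier is not expected to
  work well, matching practice).
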