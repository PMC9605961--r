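# cantimbre

Objective timbre analysis for the singing voice.

Voice teachers and phoniatricians judge whether an operatic voice is
bright or dark — tenor-like vs baritone-like, lyric vs dramatic — by ear.
That judgement lives in the 2–4 kHz *singer's formant* region, and getting
it wrong has clinical consequences: singers cast against their voice
structure risk overuse dysphonia. `cantimbre` computes the band-limited
spectral statistics that turn this judgement into numbers, for anyone
analyzing sustained sung tones: voice researchers, phoniatric
diagnostics, and singing pedagogy.

## What it computes

For a sustained tone and a voice-type band [B₁, B₂] (soprano
2300–4500 Hz; tenor/baritone/bass 2000–3600 Hz), with band energy density
p(f) = S²(f)/ΣS² and cumulative distribution P(f):

- **FHE** — frequency of half energy: the f where P(f) = 0.5 (Hz).
  Higher = brighter.
- **PHE** — position of half energy: (FHE − B₁)/(B₂ − B₁)·100 (%).
- **SC** — spectral centroid: Σ f·p(f) (Hz), plus spectral variance,
  skewness and kurtosis.
- **Co-features** — vibrato rate (Hz) and extent (cents, peak-to-peak),
  jitter and shimmer (%), formant band strength/start/stop.
- **Cohort layer** — group means, SDs, 95% reference intervals (both
  dialects), two-sample t-tests, skewness screening, correlation
  matrices, and bundled reference statistics for a published cohort of
  1723 professional opera samples.
- **Classifier** — a seed-deterministic random forest for lyric vs
  dramatic voice structure with normalized information-gain importances
  and exact additive per-sample attributions (interventional Shapley,
  local accuracy to machine precision).
- **Synthesis** — a ground-truthed sung-tone generator (harmonic
  envelope, FM vibrato, jitter/shimmer, noise) so the whole chain is
  testable without recordings.

## Worked example

Synthesize a baritone-like tone (singer's-formant cluster at 2.8 kHz,
5.5 Hz / 100 cent vibrato, 0.3% jitter, 2% shimmer, 30 dB SNR) and
analyze it:

```r
library(cantimbre)

spec <- voice_spec(f0 = 220, duration = 3, seed = 7)
syn  <- synthesize(spec, voice_band("baritone"))

extract_timbre(syn$waveform, syn$sample_rate, "baritone")
#> <timbre_features> baritone band [2000, 3600] Hz
#>   FHE 2784.6 Hz | PHE 49.04 % | SC 2769.2 Hz
#>   variance 48872 Hz^2 | skewness -0.247 | kurtosis 4.271

ctr <- track_harmonic(syn$waveform, syn$sample_rate, 220, 13L)
vibrato_features(ctr)[c("vr", "ve")]
#> VR 5.50 Hz | VE 99.2 cents   (designed: 5.5 Hz, 100 cents)

perturbation(syn$waveform, syn$sample_rate, 220)[c("jitter", "shimmer")]
#> jitter 0.60 % | shimmer 1.71 %
```

(Raw cycle-to-cycle jitter reads above the designed 0.3% because the
vibrato itself changes consecutive periods — a property of the tone, not
a measurement error.)

FHE ≈ 2785 Hz sits above the bundled baritone cohort mean (2454 Hz) —
this synthetic tone is brighter than a typical baritone, PHE saying the
same thing in band-relative terms (49% vs a cohort mean of 28%). The
vibrato designed into the tone is recovered to 0.01 Hz and < 1 cent.
Reconstructing a cohort confidence interval from published summary
statistics:

```r
reference_interval(3092, 284, 774, "ci_of_mean", round_int = TRUE)
#> [1] 3072 3112   # soprano FHE mean bounds
```

A command-line interface covers the same workflow
(`cantimbre demo --out DIR --seed 7`, plus `synth`, `extract`, `stats`,
`classify` subcommands; see `?cli_main`).

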