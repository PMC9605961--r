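Package: cantimbre
Title: Objective Timbre Parameters for the Singing Voice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of voice timbre in sustained sung tones.
    Computes band-limited spectral energy parameters over the singer's
    formant region -- frequency of half energy (FHE), position of half
    energy (PHE), spectral centroid (SC) and higher spectral moments --
    together with vibrato rate and extent, jitter, shimmer and formant
    band descriptors. Includes a ground-truthed synthetic voice generator,
    cohort descriptive statistics with reference intervals, and a random
    forest workflow for lyric versus dramatic voice structure
    classification with impurity importances and additive per-sample
    attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
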