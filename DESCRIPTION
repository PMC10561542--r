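Package: hgspeech
Title: High-Gamma ECoG Analysis of Phonological Encoding During Syllable
    Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cortical high-gamma (70-150 Hz) activity
    recorded with electrocorticography during consonant-vowel-consonant
    syllable repetition. Provides a synthetic-session generator with planted
    temporal response profiles and phonemic tuning, audio voice-onset
    detection, neural signal conditioning (notch filtering, kurtosis-based
    bad-channel screening, grid-wise common average referencing, Hilbert
    high-gamma extraction, baseline z-scored epoching), a Kalman-filter
    trend and change-point analysis with freeze/decay dynamics, hybrid
    partitioning/hierarchical clustering of response time-courses under an
    exponential distance, linear-discriminant phonemic decoding with
    minimum-redundancy-maximum-relevance feature selection, electrode-level
    encoding strength and bootstrap phonemic-preference indices, and
    group-level statistics (exact binomial chance levels and lateralization
    tests, false-discovery-rate control, chi-square distribution tests,
    logistic width regression, and within-subject ANOVA).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    MASS,
    car,
    mclust,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
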