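Package: ectmse
Title: Multiscale Entropy and Spectral Analysis of EEG Across an ECT Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking resting-state EEG complexity across an
    electroconvulsive therapy (ECT) treatment course. Implements coarse-graining
    and sample entropy (SampEn, m = 2, r = 0.2 SD) to build multiscale entropy
    (MSE) curves from 30 s artifact-free segments, Hanning-windowed FFT power
    spectra of the same segments, scale-band by region summaries
    (frontocentral SF 1-5, occipital SF 31-40), between-segment reproducibility
    correlations, and descriptive associations with clinical scores (BFCRS) and
    serum BDNF. Includes readers for EDF and matrix-form EEG plus clinical and
    ECT-course tables, a synthetic-study generator with injectable
    condition-dependent complexity effects, and an end-to-end pipeline with a
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
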