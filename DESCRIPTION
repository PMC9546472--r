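Package: circasync
Title: Circadian Rhythm Detection, Period Estimation and Phase Synchrony
    for Photosynthetic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for circadian and diel rhythms in
    photosynthetic reporter time series such as delayed chlorophyll
    fluorescence and PAM-derived Y(II)/NPQ. Provides a seeded synthetic
    panel generator (damped cosines on a growth baseline, with optional
    zeitgeber forcing), moving-average smoothing and baseline-and-amplitude
    detrending, rhythmicity calling from combined Lomb-Scargle and
    JTK-style rank tests with Benjamini-Hochberg FDR filtering, FFT-seeded
    multi-cosine nonlinear least-squares estimation of period, phase,
    amplitude and relative amplitude error, Kuramoto order-parameter phase
    synchrony over sliding windows, T-cycle phase normalization, and
    one-way ANOVA/Tukey group comparisons of rhythm parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
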