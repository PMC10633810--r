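Package: icr2dms
Title: Two-Dimensional FT-ICR Mass Spectrometry with Quadrupolar Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, processing and interpretation of two-dimensional
    Fourier transform ion cyclotron resonance (FT-ICR) mass spectra acquired
    with quadrupolar (2-omega) detection. Provides a forward model for 2D
    transients (precursor-frequency amplitude modulation, electron-capture
    products, nonsinusoidal modulation harmonics, scintillation noise and
    1-omega leakage), the magnitude-mode processing chain (Kaiser
    apodization, zero filling, 2D Fourier transform, low-rank Hankel
    denoising, 2D peak picking), structured extraction of autocorrelation,
    electron-capture, fragment-ion and precursor-ion scans, and a top-down
    proteoform workflow for variably acetylated proteins: c/z/y fragment
    libraries, isotope patterns, fragment assignment, cleavage coverage,
    per-site modification-occupancy profiles and average-charge statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
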