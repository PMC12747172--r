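Package: fnirsqc
Title: Automated Channel-Wise Signal Quality Control for fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("fnirsqc", "developers", email = "fnirsqc@example.org", role = c("aut", "cre"))
Description: Automated quality control for functional near-infrared spectroscopy
    (fNIRS) recordings. Converts dual-wavelength light intensity to optical
    density and hemoglobin concentration changes via the modified Beer-Lambert
    law, extracts a subject-specific cardiac frequency band by spectral fitting
    (Welch periodogram, Savitzky-Golay smoothing, aperiodic 1/f flattening,
    Gaussian peak fitting), renders standardized Morlet wavelet scalograms with
    the cardiac band anchored at a fixed image row, and classifies segments as
    high or low quality with a compact convolutional network trained under a
    subject-wise protocol. Includes coefficient-of-variation and scalp coupling
    index baselines, a statistical comparison suite (McNemar, Friedman,
    Wilcoxon signed-rank with Benjamini-Hochberg correction, Cliff's delta),
    a seeded synthetic recording generator with ground-truth labels, readers
    and writers for SNIRF and Homer-style .nirs files, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
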