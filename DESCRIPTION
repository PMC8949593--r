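Package: AmorphQuant
Title: Quantification of Amorphous Drug Content from NIR and Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric quantification of amorphous drug content in
    polymer-based solid dispersions (e.g. laser-sintered printlets) from
    near-infrared and Raman spectra. Provides a SummarizedExperiment-based
    container for spectra, a seeded generator of realistic NIR/Raman mixture
    spectra with crystalline/amorphous solid-state signatures, spectral
    preprocessing operators (Savitzky-Golay derivatives, standard normal
    variate, Whittaker asymmetric-least-squares baseline correction,
    peak-area normalization, region selection, mean-centering), partial
    least squares (PLS1, NIPALS) calibration with leave-one-out
    cross-validation and ICH-style validation metrics, Hotelling T-squared
    score-space admissibility diagnostics, and powder-flow characterization
    (bulk/tapped density, compressibility index, Hausner ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
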