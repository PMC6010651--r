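Package: hoseeg
Title: Higher-Order Spectral Analysis of EEG for Epileptic State Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing epilepsy states (healthy, interictal, ictal)
    from single-channel EEG using higher-order spectra. Implements direct-FFT
    and indirect (third-order cumulant) bispectrum estimation, bicoherence,
    principal-domain geometry with the twelve bispectral symmetries, Hinich's
    Gaussianity and linearity tests, a 47-feature band-region scheme over the
    bi-frequency plane, genetic-algorithm and Student-t feature selection,
    least-squares support vector machine classification with one-versus-one and
    error-correcting output-code multiclass schemes, and an end-to-end
    experiment pipeline. Includes a synthetic generator of Bonn-style EEG
    records with controllable quadratic phase coupling so the whole pipeline is
    testable without external recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
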