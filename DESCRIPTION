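Package: hybret
Title: Spectral Models, Ratio Imaging and Plate Analytics for Hybrid
    BRET-FRET Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for hybrid BRET-FRET (hyBRET) biosensors
    that report kinase activity by both fluorescence and bioluminescence
    resonance energy transfer. Provides closed-form forward models of
    donor/acceptor emission spectra, estimation of energy-transfer
    efficiencies by bounded nonlinear least squares with bootstrap
    confidence envelopes, dual-channel ratiometric image processing with
    intensity-modulated display rendering and linear unmixing,
    luminescence microplate analytics (Z-prime factor, Hill and coupled
    ERK/viability dose-response models), and a seeded synthetic-data
    generator for spectra, image stacks and plates with recorded ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
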