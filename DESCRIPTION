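Package: ellmanfic
Title: Ellman-Assay AChE Inhibition Screening, 4PL Dose-Response and
    FIC Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for colorimetric (Ellman) acetylcholinesterase
    inhibition screens: reduction of kinetic plate-reader absorbance traces to
    percent inhibition with spontaneous-drift correction, four-parameter
    logistic dose-response fitting with closed-form inversion to IC ladders
    (IC10..IC90), fixed-partner combination designs scored by fractional
    effect terms and the fractional inhibitory concentration (FIC) combination
    index under named classification schemes, isobologram coordinates,
    cytotoxicity selectivity indices, and a seeded synthetic plate generator
    (Loewe-additive combinations with tunable interaction strength) so every
    stage is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    numDeriv,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
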