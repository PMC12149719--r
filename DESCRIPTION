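Package: flashdose
Title: Pencil-Beam-Scanning Dose-Rate Simulation and FLASH Effect Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pencil-beam-scanning (PBS) proton delivery on the
    isocenter plane: 2D Gaussian spot superposition dose maps, delivery
    timelines with repainting and multiple fields, field-average and
    threshold-based PBS dose rates, and dose-rate-volume histograms. Also
    implements harmonized preclinical FLASH-effect metrics (crypt
    regeneration, survival at fixed days, moist desquamation with
    three-band skin-toxicity harmonization), a validated study-record
    schema for murine ultra-high-dose-rate experiments, spreadsheet-style
    effect sheets, and deterministic synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
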