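Package: mwisar
Title: Frequency-Domain Microwave ISAR Imaging for Biomedical Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward and inverse modelling for bistatic microwave inverse
    synthetic aperture radar (ISAR) imaging of water-coupled biological
    phantoms, aimed at laboratory feasibility studies for brain stroke
    detection. Implements the bistatic radar forward model on a rotating
    polar scene (sinogram synthesis over a frequency sweep), sensitivity
    matrix assembly, Moore-Penrose pseudo-inverse image reconstruction via
    truncated SVD, windowed-IFFT range compression, Cole-Cole dielectric
    dispersion of tissues and matching media, tissue loss budgets and
    resolution formulas, synthetic phantom generators, VNA measurement
    ingestion (Touchstone and CSV), rod-based medium calibration, and an
    end-to-end reconstruction pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    pracma,
    yaml,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
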