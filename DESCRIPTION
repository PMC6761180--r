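Package: migrEIS
Title: Impedimetric Monitoring of Tumor-Cell Migration on High-Density
    Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for label-free, impedance-based monitoring of
    cell migration out of 3D micro-tumor spheroids placed on high-density
    microelectrode arrays. Computes per-electrode relative impedance spectra
    against cell-free baselines, extracts spectral maxima, calls covered
    electrodes, maps coverage across the 6 x 7 electrode grid, and summarises
    wells over time. Discriminates migration from proliferation with a
    reference-calibrated four-quadrant scheme and classifies wells
    automatically by principal-component reduction of twelve time-dependent
    features followed by fuzzy c-means clustering. Includes an agent-based
    simulator of spheroid cell egress with tunable migration and
    proliferation phenotypes, rendered into impedance recordings through an
    equivalent-circuit electrode model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
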