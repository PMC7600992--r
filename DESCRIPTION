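Package: immunogradient
Title: Tumor-Stroma Interface Immunogradient Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hexagonal-grid spatial analytics for immune-cell infiltration at
    the tumor-stroma interface of segmented whole-slide images. Builds a
    hexagonal sampling lattice over a tissue-class raster, detects the tumor
    edge, assigns signed ranks by lattice distance, extracts interface zones,
    and computes Immunogradient indicators (Center of Mass, per-aspect and
    intratumoral cell densities) for CD8+, CD20+ and CD68+ cells. Provides
    cohort-level survival statistics (optimal log-rank cutoffs, Kaplan-Meier,
    stepwise Cox regression, leave-one-out validation), construction of the
    CD8-CD20 Immunogradient score and the immuno-interface score (IIS), and a
    synthetic-data generator (inhomogeneous Poisson tissue simulation,
    proportional-hazards cohorts) so every pipeline stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
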