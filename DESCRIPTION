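Package: sclipid
Title: Single-Cell Lipid Profiling: Spectrum Matching, Quality Control and
    Heterogeneity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-processing pipeline for high-throughput single-cell lipid
    profiling by direct-infusion mass spectrometry (e.g. liquid extraction
    surface analysis, LESA-MS). Takes per-well centroid spectra, matches a
    panel of sum-composition lipid targets by ppm mass tolerance, estimates
    signal-to-noise, applies sample-level quality control (failed-well and
    doublet exclusion), lipid-level QC filters (mass accuracy, S/N,
    cell-number standard-curve linearity, presence fraction), total-signal
    normalization with plate-batch and injection-order checks,
    cross-experiment confidence tiering, and single-cell heterogeneity
    statistics (genotype contrasts, abundance stratification, fold changes,
    PC/PE ratio). Includes a seeded synthetic-spectrum generator emulating
    FACS-dispensed single-cell wells, extraction blanks, pooled QCs and
    multi-cell standard-curve wells, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse
Config/testthat/edition: 3
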