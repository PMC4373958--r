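Package: virtualqa
Title: Virtual Delivery Quality Assurance with a Helical Diode Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual cylindrical-phantom study of radiotherapy delivery
    quality assurance. Builds voxelized phantom geometry with cylindrical
    target and organ-at-risk masks, computes five-field conformal plans with a
    documented closed-form beam model, simulates measurements on a 1,386-diode
    helical array under configurable error models (calibration offset,
    field-size-dependent diode response, rigid setup shift, reading noise),
    evaluates 2D and 3D gamma passing rates (global normalization, 5%
    threshold), reconstructs a perturbed 3D dose by back-projecting diode-level
    discrepancies, and derives DVH metrics (Dmean, D50, D95), dose deviations
    and their statistical comparisons (t-test, one-way ANOVA, Pearson
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
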