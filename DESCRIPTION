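Package: bactoline
Title: Single-Antibody Droplet Bioassay Analysis for Anti-Bacterial
    Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of droplet-microfluidic single-antibody bioassays in
    which antibody-secreting cells are co-encapsulated with bacteria-coated
    magnetic nanoparticle aggregates (bactolines). Implements a mass-action
    equilibrium model of fluorescence relocation with a Hook effect,
    calibration of per-droplet curve features (y_max, x_max) to apparent
    dissociation constants and epitope densities, per-droplet trace
    processing with an interior-maximum filter, two-density kinetic ELISA
    affinity estimation after Beatty, cohort-level repertoire statistics
    (secreting-cell frequencies, class-switch ratios, cross-reactivity,
    3x3 affinity/epitope heat maps), and a ground-truth synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
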