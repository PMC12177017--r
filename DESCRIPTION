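Package: ethoacc
Title: Behaviour Classification from Animal-Borne Tri-Axial Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating accelerometer-based ethograms
    for slow-moving marine animals such as sea turtles. Provides a seeded
    simulator of labelled tri-axial acceleration recordings (posture, limb-beat
    oscillation, per-individual variation, tag-position effects, analogue to
    digital quantisation), logger and annotation CSV ingestion with UTC
    synchronisation and bout trimming, fixed-length window segmentation with
    downsampling, the standard 18 per-window summary metrics (per-axis moments
    and extrema, ODBA, VeDBA, pitch and roll statistics), random-forest
    behaviour classification with individual-blocked cross-validation and
    up-sampling, maximum-likelihood beta regression with Wald tests and
    Tukey-adjusted pairwise contrasts for comparing device placements and
    sampling frequencies, and drag-coefficient utilities for quantifying the
    hydrodynamic cost of tag placement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
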