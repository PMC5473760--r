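Package: wormscatter
Title: Dark-Field Scattering Densitometry of C. elegans Fat Stores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies relative fat content of C. elegans from dark-field
    micrographs. Implements phantom-based illumination correction,
    intensity-threshold worm segmentation with manual outlines, scattering
    density and Oil Red O pseudodensity measurement, high-pass/percentile
    colocalization against Nile Red via the Sorenson-Dice coefficient,
    cohort statistics (ANOVA with Bonferroni pairwise tests, cohort-mean
    validation fits, paired fasting comparisons), developmental time-course
    assembly with cross-objective stitching, and a ground-truthed synthetic
    scene generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
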