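Package: gliaquant
Title: Quantification of Astrocyte Reactivity in the Glaucomatous Optic Nerve Head
Version: 0.1.0
Authors@R:
    person("Glial Lamina", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the heterogeneous reactivity of optic nerve head
    astrocytes in experimental glaucoma. Implements 3D detection of
    axon-derived, dye-labeled mitochondria enclosed within astrocyte cytoplasm
    in two-channel confocal stacks (binarization, per-slice median filtering,
    3D connected-component labeling, a voxel-tight enclosure test, and
    volume-fraction quantification), a single-cell qPCR workflow (control-gene
    quality filtering, delta-Ct expression, whole-population comparison with
    Bonferroni correction, pooled z-normalization and confidence-interval
    reactivity calls), cohort-level statistics (cumulative intraocular
    pressure, normality-gated two-group tests, ANOVA with Tukey-Kramer,
    least-squares regression with confidence bands), automated retinal
    ganglion cell nucleus counting, and seeded synthetic-data generators that
    emulate every input type with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
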