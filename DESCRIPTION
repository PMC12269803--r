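Package: axonmap
Title: Whole-Brain Axonal Projection Density Mapping with Behavioral and
    Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mesoscale axonal projections from serial
    coronal fluorescence sections: quarter-wise clamped gamma intensity
    normalization, rolling-ball background subtraction, binary-threshold axon
    segmentation, and hierarchical atlas-region density metrics (axon density,
    relative density, proportional density), with cortical-network aggregation
    and ipsilateral/contralateral ratios. Includes synthetic-data generators
    (toy atlases, axon-labeled brains with known ground truth, open-field
    trajectories, rotarod latencies, grouped assay values), open-field zone
    and kinematics analysis, rotarod aggregation, analyte-per-protein
    normalization, and the group-level statistics used in projection-mapping
    studies (one-way ANOVA with Tukey HSD, unpaired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
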