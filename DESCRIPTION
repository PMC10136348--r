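Package: bsiquant
Title: Bone Scan Index Quantification for Planar Bone Scintigraphy
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic quantification of the bone scan index (BSI) on
    planar whole-body bone scintigraphy: seed-pixel intensity thresholding,
    border-following extraction of regions of interest with Green's-theorem
    (shoelace) areas, manual exclusion of non-metastatic hotspots, and
    silhouette-based normalisation to a percentage of the imaged skeleton.
    Ships a synthetic phantom generator with pixel-level ground truth, a
    proportional-hazards cohort simulator calibrated to a multicentre
    metastatic castration-resistant prostate cancer population, and the
    matching prognostic pipeline: Kaplan-Meier estimation, centre-adjusted
    Cox regression with robust standard errors, and forward stepwise AIC
    model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
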