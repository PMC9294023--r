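Package: alsclust
Title: Data-Driven Radiological Subtyping of ALS from Regional Integrity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies radiological subtypes of amyotrophic lateral sclerosis
    from imaging-derived tabular metrics. Reduces cortical thickness, volumetric
    and fractional anisotropy tables to 74 bilateral-averaged variables,
    computes min-max scaled composite integrity scores for 15 anatomical
    regions of interest, clusters patients with a from-scratch two-step
    procedure (CF-tree pre-clustering, centroid-linkage agglomeration and
    BIC-based automatic selection of the number of clusters), evaluates
    silhouette cohesion and predictor importance, and contrasts clinical and
    genetic profiles between clusters with continuity-corrected and Pearson
    chi-square tests. Includes a synthetic cohort generator emulating a
    two-subtype ALS study population for end-to-end testing without patient
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
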