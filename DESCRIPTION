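Package: fxiselect
Title: Factor XI Activity-Related Plasma Protein Discovery by
    Fractional-Polynomial LASSO
Version: 0.1.0
Authors@R:
    person("GMP-VTE", "Reanalysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering plasma proteins associated with factor XI
    coagulant activity (FXI:C) in venous thromboembolism cohorts measured on
    targeted proteomics (Olink NPX) panels.  The analytical core expands every
    protein into a fractional-polynomial basis, fits a covariate-adjusted
    LASSO with ten-fold cross-validated lambda selection, and ranks selected
    proteins by the scale-invariant lambda ratio (entry lambda on the
    regularization path divided by the cross-validation optimal lambda).
    Companion modules provide cohort preprocessing (exclusion rules,
    normality transforms, FXI:C strata, paired timepoint comparison), the two
    prescribed sensitivity analyses (DOAC non-users; APTT-discordant
    exclusion), correlation-augmented hypergeometric pathway enrichment
    against a measured-protein background, Markov clustering and MCODE dense
    complex detection on protein-protein interaction graphs, a synthetic
    two-timepoint VTE-like cohort generator with planted ground truth, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
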