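Package: trussmorph
Title: Truss-Network and Geometric Morphometrics for Phenotypic Stock Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based morphometric analysis of fish body shape aimed at
    phenotypic stock discrimination. From 2D landmark configurations the package
    builds the full truss network of inter-landmark distances, applies log and
    allometric (Elliott) size correction, and quantifies population structure by
    correlation-matrix PCA with Kaiser retention, canonical discriminant function
    analysis, discriminant analysis of principal components (DAPC) with membership
    probabilities, and one-vs-rest ROC/AUC performance grading. A geometric
    morphometrics layer provides generalized Procrustes superimposition, Procrustes
    ANOVA, shape PCA, pairwise group mean-shape permutation tests, thin-plate-spline
    warps with bending energy and relative warps, group-level warp summary scores,
    and landmark-subset modularity via the Escoufier RV coefficient. A synthetic
    landmark-data generator with known ground truth makes the whole pipeline
    testable without external data. Reads and writes TPS digitization files and
    delimited landmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
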