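Package: moesubtype
Title: Semi-Supervised Mixture-of-Experts Subtyping of Cortical Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven discovery of gray-matter atrophy subtypes in the
    Alzheimer's disease continuum from regional cortical thickness. Fits a
    semi-supervised mixture of experts that couples K linear max-margin
    classifiers (cognitively normal controls as a shared negative anchor)
    with fuzzy C-means memberships over patients, after covariate
    residualization of Desikan-Killiany ROI thickness against a
    control-only linear model. Mild cognitive impairment subjects are
    mapped to subtypes by smallest hyperplane distance. Includes a seeded
    synthetic cohort generator with planted subtypes and longitudinal
    conversion events, visit-screening rules for at-risk sets, and
    conversion/APOE reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
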