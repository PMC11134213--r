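Package: dyadomics
Title: Maternal-Placental-Fetal Metabolome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating quantitative metabolome panels measured
    across the maternal-placental-fetal unit in mother-infant dyads.
    Implements detection-rate filtering and dyad pairing for compartment
    concentration tables, within- and between-metabolome Spearman screens
    with Benjamini-Hochberg false discovery rate control, covariate-adjusted
    rank-based (Wilcoxon-score) linear regression, covariate-residualized
    canonical and sparse partial least squares with Q2 leave-one-out
    component selection and a permutation test on the covariance of the
    first latent variate pair, relevance networks between metabolome blocks,
    and multinomial logistic models of a three-level neurodevelopmental
    outcome with simulated probability curves. A synthetic cohort generator
    with recorded ground truth supports method validation when raw cohort
    data are not available.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
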