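Package: peaks2func
Title: Functional Analysis of Untargeted LC-MS Peak Tables
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns untargeted LC-MS1 peak intensity tables into pathway and
    metabolite-set level insight without requiring compound identification.
    Implements putative adduct-based peak annotation, empirical-compound
    grouping by retention time, mummichog-style pathway activity prediction
    with a permutation-calibrated Gamma null, enrichment of arbitrary peak
    groups, weighted p-value combination for joint gene-metabolite pathway
    analysis, functional meta-analysis across datasets (pathway-level
    integration and peak pooling), debiased sparse partial correlation
    (DSPC) networks, technical-replicate merging, background-feature
    filtering, compound-name normalization, and readers for peak tables,
    ranked peak lists, GMT libraries and mzTab-M 2.0.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
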