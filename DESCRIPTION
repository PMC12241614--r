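Package: netage
Title: Individual-Specific Gene Regulatory Networks and Aging Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers individual-specific transcription-factor to gene regulatory
    networks by message-passing refinement of a motif prior with protein-protein
    interaction and coexpression evidence (PANDA), followed by single-sample
    linear interpolation (LIONESS). Downstream tools quantify differential
    TF-targeting of genes with age (covariate-adjusted linear models with
    empirical-Bayes moderated t-statistics), smoking-history aging trajectories,
    pre-ranked gene set enrichment, a LASSO-penalized Cox aging signature built
    from pathway targeting scores, and matching of differential-targeting gene
    lists against drug regulatory signatures with a resampling null. A synthetic
    cohort generator with planted regulatory aging effects makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    limma,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
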