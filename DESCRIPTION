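Package: connclass
Title: Classification and Attribution of Multi-Site Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation, classification and attribution of resting-state
    functional connectivity (FC) case-control cohorts. Generates multi-site
    synthetic cohorts with planted connection-wise effect sizes, builds
    Pearson FC matrices and sparsified connectome graphs, runs support vector
    machine and graph convolutional network classifiers under stratified
    cross-validation with permutation testing, attributes classifier decisions
    with an edge-mask explainer and a region-ablation study, and performs the
    mass-univariate connection-wise stage (covariate residualization, pooled
    t-tests, Benjamini-Hochberg FDR, Cohen's d, region degree summaries and
    lightweight site harmonization).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
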