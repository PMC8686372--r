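Package: ctginterp
Title: Interpretable Analysis of Antepartum Cardiotocography Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpretable fetal-status assessment from antepartum
    cardiotocography (CTG) feature tables: reading and validating the standard
    21-feature CTG table, Spearman rank-correlation screening and per-bin
    class-proportion profiles, class-distribution-guided discretization with a
    forward-stepwise association-rule miner designed for rare pathological
    cases, and a maximum-likelihood structural-equation-model engine (LISREL
    parameterization) producing standardized solutions, Wald statistics, fit
    indices and direct/indirect effect decompositions. A synthetic CTG
    generator with known class imbalance, planted association rules and a
    latent-factor covariance structure supports fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    numDeriv,
    withr,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
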