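Package: repliconn
Title: Replicability Assessment for Connectome-Based Predictive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how likely a cross-validated brain-behavior
    prediction is to replicate in an independent sample of the same size.
    Provides an empirical engine that repeatedly splits a cohort into disjoint
    discovery and replication halves, fits ridge regression under nested
    cross-validation on the discovery half, evaluates the refit model on the
    replication half, and aggregates the outcomes into a replication
    probability per sample size; a theoretical engine that predicts required
    sample sizes from an observed effect size via the K-prime predictive
    distribution of the replication t statistic; and a synthetic connectome
    generator with planted, variance-calibrated effects for validating the
    whole pipeline without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
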