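Package: lipistage
Title: Lipid-Biomarker Panels and Machine Learning for Colorectal Cancer Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for ordinal colorectal-cancer staging from
    plasma lipidomic feature tables merged with chemokine, gene-status and
    clinical covariates. Implements sparse multiple linear regression with
    expectation-maximization feature pruning (MLR-EM, an iteratively
    reweighted ridge scheme with a tunable sparsity coefficient), a
    Bayesian-regularized single-hidden-layer neural network trained by
    evidence-framework hyperparameter re-estimation, truth-table and
    tolerance-accuracy evaluation of rounded ordinal predictions,
    Kaplan-Meier / log-rank survival comparison across disease groups, and a
    seeded synthetic-cohort generator that emulates the statistical structure
    of such studies so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
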