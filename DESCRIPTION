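Package: gnnsurv
Title: Discrete-Time Survival Prediction on Patient Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds patient similarity networks from combined gene-expression
    and clinical covariates using a locally scaled exponential similarity
    kernel, and trains graph neural networks (GCN, GraphSAGE, GAT) with
    discrete-time survival likelihoods (Logistic Hazard and PMF) for
    right-censored time-to-event prediction. Includes censoring-aware
    evaluation (time-dependent concordance, inverse-probability-of-censoring
    weighted Brier score and its integral), survival-time discretization and
    interpolation utilities, a synthetic cohort generator with
    cluster-structured survival, and a repeated random-split experiment
    pipeline with inductive subgraph evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
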