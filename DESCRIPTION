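Package: maveImpute
Title: Imputation and Refinement of Missense Variant-Effect Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Back-end pipeline for completing variant-effect maps from
    multiplexed assays of variant effect (MAVEs). Rescales raw function
    scores to the stop/synonymous anchor scale, reciprocal-corrects
    apparently-adaptive variants, trains a per-protein gradient boosted
    tree regressor on physicochemical, substitution-matrix, positional-mean
    and optional external-predictor features, imputes scores for unmeasured
    missense variants, regularizes per-variant standard errors against a
    score-dependent prior, refines poorly measured scores by
    inverse-variance weighting, and renders the completed position by
    substitution map. Includes a seeded synthetic MAVE dataset generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    data.table,
    xgboost,
    randomForest,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
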