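Package: psetf
Title: Tensor-Factorization Link Prediction for Polypharmacy Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts polypharmacy side effects (adverse reactions specific
    to drug pairs) by casting them as a multirelational link-prediction
    problem over a drug/gene knowledge graph and factorizing the resulting
    triple tensor.  Implements the DistMult, ComplEx and SimplE scoring
    models with 1vsAll/KvsAll training, plateau learning-rate scheduling
    and early stopping; two graph constructions that differ in how
    single-drug (monopharmacy) side effects are encoded (self-loop edges
    versus PCA-reduced n-hot feature initialization); per-side-effect
    holdout splitting with matched negative sampling; ranking (filtered
    MRR, hits@k) and classification (AUROC, AUPRC, AP@50) evaluation; a
    Sobol-then-Bayesian hyperparameter search; and a synthetic generator
    that plants low-rank trilinear structure in miniature raw tables so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
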