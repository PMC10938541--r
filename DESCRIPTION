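Package: tcrstrat
Title: Stratifying Cancer Patients from Healthy Donors by Peripheral-Blood
    TCR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying peripheral-blood T-cell receptor (TCR)
    repertoires into clinical groups (ovarian-cancer patients versus healthy
    donors). Reads AIRR and MiXCR-style clonotype tables, aggregates clones by
    CDR3 amino-acid sequence, downsamples repertoires to a common UMI depth,
    computes clonal diversity indices (Gini, Gini-Simpson, inverse Simpson,
    Hill numbers), and builds a clone-by-sample frequency matrix. Two feature
    selection routes reduce the matrix to a handful of discriminative clones:
    a top-down route (most-shared clones, select-from-model, backward
    sequential feature selection) and a top-clones route seeded by the most
    prevalent CDR3s in public databases. A model search over eight classifier
    families with Gaussian-process Bayesian hyperparameter optimization and
    bootstrap evaluation selects the final model by ROC AUC. Selected clones
    are annotated with invariant T-cell subtype calls (iNKT, MAIT) from V/J
    gene usage and tested for enrichment in a tumor-infiltrating-lymphocyte
    database via a bootstrap occurrence null. A synthetic-data module
    generates cohorts, public-database fixtures and TIL databases with the
    statistical structure the analysis assumes, so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    ranger,
    xgboost,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
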