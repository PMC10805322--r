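Package: modelcongr
Title: Congruence Quantification and Selection of Cancer Models from Transcriptomic Data
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how faithfully candidate cancer models (cell lines,
    patient-derived xenografts and organoids) recapitulate a target tumor
    subtype from bulk transcriptomic data, and ranks them for selection.
    Tumor and model expression matrices are first harmonized (quantile
    normalization, empirical-Bayes batch correction, or a contrastive-PCA plus
    mutual-nearest-neighbors aligner). A sparse discriminant analysis fitted by
    penalized optimal scoring on the tumor cohort yields a one-dimensional
    projection on which each model receives an assignment probability and a
    robust median/MAD deviance score with bootstrap confidence interval.
    Pre-selected models are then dissected mechanistically: differential
    expression between the two tumor subtypes, preranked gene-set enrichment,
    and pathway- and gene-level deviance scores with empirical p-values produce
    the final pathway-aware ranking. A synthetic-data module generates
    two-subtype tumor cohorts and planted candidate models so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
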