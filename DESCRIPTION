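Package: gaitshift
Title: Smartphone Accelerometer Gait Classification Under Simulated
    Visual Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for classifying walking
    condition from pocket-smartphone tri-axial accelerometer recordings,
    where the six conditions correspond to alcohol-impairment simulation
    goggles of increasing simulated blood-alcohol range. Provides a
    synthetic cohort generator with condition-dependent gait perturbations,
    raw-recording input/output, signal synchronisation and steady-gait
    extraction via autocorrelation periodicity, sliding-window dataset
    assembly with white-noise augmentation, a zoo of five small
    Conv1D/BiLSTM/self-attention sequence classifiers with masked-prediction
    encoder pretraining (implemented natively, trained with Adam), and a
    full evaluation suite: confusion matrices, class-wise and aggregate
    indicators, Wilson, bootstrap and Student-t confidence intervals,
    within-traversal cross-validation, and input-channel ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
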