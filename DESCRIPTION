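Package: prostir
Title: Intermediate-Reasoning Prognostication of Prostate Cancer
    Biochemical Recurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pre-surgical prognostication of biochemical recurrence (BCR)
    after radical prostatectomy from histopathology patch-composition
    features. Implements a visual-codebook feature bank over tissue patches
    (tiling, embedding, k-means codebook, per-cluster impact scores), a
    clinically informed reasoning-oriented grading scale built from Gleason
    pattern pairs adjusted by training-set outcomes, an intermediate ridge
    regression predicting that scale from composition vectors, and final
    linear BCR models with logistic recalibration. Ships a full clinical
    evaluation suite (patient-level bootstrap AUROC, Brier score,
    calibration curves, decision-curve analysis, cohort characterisation
    tests) and a synthetic slide and cohort generator with an
    inter-institution domain-shift mode so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
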