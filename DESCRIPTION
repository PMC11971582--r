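Package: crscore
Title: Automated Scoring of Clinical-Reasoning Documentation in Admission Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for automated assessment of clinical-reasoning
    documentation quality in hospital admission notes using the
    differential-diagnosis (D) and explanation-of-reasoning (EA)
    components of the Revised-IDEA rubric. Provides named-entity
    recognition over five rubric entity types (diagnosis, diagnostic
    category, prioritization, data, linkage), a deterministic logic
    mapping from entities to D scores, one-vs-rest note classifiers with
    runtime text augmentation, inverse-class-frequency oversampling and
    operating-point selection, a stepwise D composition rule and binary
    EA2 scoring, plus a full evaluation harness: SemEval-2013 Task 9
    Type-matching NER metrics, AUROC/AUPRC, stratified k-fold
    cross-validation and two-way mixed-effects intraclass correlation.
    A seeded synthetic-note generator with gold entity spans and gold
    labels makes every pipeline exercisable without access to protected
    health information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
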