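Package: protoact
Title: Prototype-Based Temporal Transformer Decoding of Surgical Activity
    from Video Frame Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decodes elements of intraoperative surgical activity
    (subphases, gestures, skill levels) from per-frame deep feature
    streams of surgical video. Implements a two-stream (appearance and
    motion) temporal transformer encoder with learned class prototypes
    trained by a supervised contrastive (InfoNCE) objective over cosine
    similarities, video-level Monte Carlo cross-validation, and
    full-video inference with test-time augmentation, cross-fold
    ensemble bagging, entropy-based abstention and gap-based temporal
    event chaining. Includes one-vs-rest ROC/AUC, positive predictive
    value and segmental F1 evaluation, synthetic feature-stream
    generators for end-to-end testing, and logistic-regression
    association of decoded skill with binary patient outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
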