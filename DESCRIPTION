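Package: cardiovoice
Title: Heartbeat-Synchronised Fusion of Cardiovascular and Voice Features
    for Cognitive Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trinary (low/medium/high) cognitive-workload
    classification from beat-by-beat cardiovascular measures and
    formant-track voice features. Implements delta/acceleration dynamic
    feature expansion, heartbeat-synchronised formant statistics,
    feature-level fusion of the two modalities, per-participant one-vs-rest
    margin and tree-ensemble classifiers with beat-level and sequence-level
    soft-score decisions, leave-one-screen-out evaluation with
    misclassification and mistrust rates, and a synthetic Stroop-style
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
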