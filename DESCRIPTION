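Package: mibci
Title: Motor Imagery EEG Decoding with Diagonal State-Space Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular motor-imagery brain-computer-interface pipeline: seeded
    synthetic EEG generation with event-related desynchronization and common
    artifact classes, artifact-robust preprocessing (Chebyshev type 2 band-pass,
    artifact subspace reconstruction, common average reference, epoching and
    cross-session normalization), stacked Morlet and common-spatial-pattern
    feature extraction, a diagonal structured state-space sequence (S4D)
    classifier with Monte-Carlo-dropout confidence, a replay-driven online
    runtime with a smoothing transfer function, a closed-loop training-game
    evaluator, and latency / information-transfer-rate analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
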