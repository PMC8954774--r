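Package: heartprint
Title: ECG-Based Biometric Identification and Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for evaluating the electrocardiogram (ECG)
    as a biometric trait across two acquisition sessions. Generates synthetic
    two-session finger-ECG cohorts with subject-specific heartbeat morphology,
    inter-session drift and realistic noise; filters and segments recordings
    into fixed-length cardiac-cycle templates with outlier-cycle elimination;
    builds time-frequency scalogram image templates from a generalized Morse
    wavelet transform; reduces concatenated subject templates with FastICA;
    and evaluates closed-set identification (LDA, kNN, decision tree, SVM, and
    Manhattan 1-NN matching) and distance-threshold authentication with
    leave-one-out impostor scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    class,
    rpart,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
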