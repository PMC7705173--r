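Package: gaitfuse
Title: Hybrid EEG-EMG Gait Phase Decoding with Bayesian Belief Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding walking phases (right swing, left swing,
    double stance) from synchronized electroencephalography (EEG) and
    electromyography (EMG) recordings. Implements sliding-window feature
    extraction for both modalities, long short-term memory (LSTM) sequence
    decoders trained per modality, and decision-level fusion of the two
    classifiers by Bayesian belief weighting calibrated from validation-set
    confusion matrices. Includes a seeded synthetic treadmill-walking
    generator (foot-switch contacts, gait-locked EMG bursts, gait-locked
    low-frequency cortical modulations), simulators for temporary
    (fatigue-like attenuation) and permanent (channel loss, attenuation,
    additive noise at target signal-to-noise ratio) EMG impairment, and
    sample-by-sample evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
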