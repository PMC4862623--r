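Package: cefp
Title: Common EEG-Fingerprint Models of Deep-Brain BOLD Activity for Neurofeedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a deep-brain region's fMRI-BOLD time course from a single
    EEG electrode via a delay-embedded, frequency-banded ridge regression (the
    "EEG fingerprint", EFP). Builds a subject-general common model (cEFP) by
    one-class selection of homogeneous sessions using hierarchical clustering of
    individual model coefficients, runs the model as a streaming neurofeedback
    signal generator with an auditory-volume feedback mapping, and evaluates
    neurofeedback success with per-subject tests, a 2x2 mixed ANOVA and Fisher's
    exact test. Includes a synthetic paired EEG/BOLD session generator with
    known ground truth, a Stockwell time-frequency front end, equal-area
    frequency banding, and minimal EDF/BrainVision readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
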