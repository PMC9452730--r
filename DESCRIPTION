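Package: rtnf
Title: Simulated Real-Time fMRI Neurofeedback with Subject-Independent
    Brain-State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully simulatable real-time fMRI neurofeedback
    pipeline. Generates synthetic block-design BOLD runs (canonical
    double-gamma HRF, AR(1) noise, low-frequency drift, tutor/patient
    activation patterns with controllable similarity), performs offline and
    abbreviated online preprocessing, builds a linear support vector machine
    brain-state classifier with effect-map feature selection and
    leave-one-run-out cross-validation, simulates a per-volume closed
    feedback loop (thermometer display and tiered monetary reward), and
    implements the accompanying learning and clinical statistics including
    an exact one-sample Wilcoxon signed-rank test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    RNifti,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
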