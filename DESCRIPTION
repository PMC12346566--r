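Package: lungrx
Title: Respiratory Sound Diagnosis and Synthetic Prescription Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular respiratory-care toolkit: MFCC feature pipelines for lung
    auscultation audio, a class-conditional synthetic sound generator, a
    fidelity-gated class-balancing augmentation pipeline, a hybrid
    CNN-LSTM-attention eight-class diagnoser built from first principles with
    hand-verified gradients, simulated molecular-biomarker fusion at the
    penultimate layer, a rule-based synthetic prescribing cohort generator with
    renal pharmacokinetic dose adjustment, a multi-output drug/dosage/frequency
    recommender, and evaluation protocols (leave-one-subject-out, grouped k-fold,
    SNR robustness sweeps, ablations, Cohen's kappa, Wilson intervals) with
    attention-trace and feature-attribution explainability.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    ranger,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
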