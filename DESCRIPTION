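Package: pttsdb
Title: Pulse Transit Time Indices for Paediatric Sleep-Disordered Breathing Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-beat pulse transit time (PTT) from ECG and
    photoplethysmography timing, computes the smoothed PTT2 channel, PTT
    arousals and the PTT arousal index, and the respiratory swing of the PTT
    signal, together with oximetry desaturation (dip) indices and a
    four-level oximetry risk category. Records are classified into sleep
    study categories (normal, primary snoring, upper airway resistance
    syndrome, obstructive sleep apnoea, abnormal other) from oximetry plus
    video annotations, and screening thresholds for the PTT indices are
    evaluated by train/test ROC analysis with bootstrap confidence
    intervals. A seeded synthetic-cohort generator produces beat series,
    waveforms, oxygen saturation traces and annotations with known ground
    truth so that every stage of the pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
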