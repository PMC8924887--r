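Package: cvfatigue
Title: Physical Fatigue Assessment from Heart Rate Variability and Pulse
    Arrival Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing exercise-induced physical fatigue from
    synchronized electrocardiogram (ECG) and pulse-wave recordings obtained
    during a structured cycle-ergometer session.  Detects ECG R-peaks with a
    Hamilton-Tompkins style detector, locates pulse-wave onset fiducials,
    derives beat-to-beat pulse arrival time (PAT) and time-domain heart rate
    variability measures (SDNN, RMSSD), normalizes PAT to a reference
    systolic blood pressure, builds a family of phase-normalized
    subparameters, screens them with leave-one-out decision stumps, and
    classifies subjects into mildly versus significantly fatigued groups
    with a linear maximum-margin boundary.  A seeded synthetic-cohort
    generator reproduces the statistical structure of a two-state
    (rested / physically fatigued) measurement day so that every pipeline
    stage can be exercised end-to-end without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
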