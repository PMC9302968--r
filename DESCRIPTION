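Package: erdtms
Title: Closed-Loop Sensorimotor-Rhythm Neurofeedback with State-Dependent
    Paired-Pulse TMS, at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a closed-loop bivariate EEG-neurofeedback
    experiment in which dual-coil transcranial magnetic stimulation (TMS) is
    triggered by the instantaneous bilateral sensorimotor-rhythm
    event-related desynchronization (SMR-ERD).  Provides a causal online ERD
    estimator (band-pass/notch filtering, large Laplacian, 1-s FFT band
    power, 5-window smoothing), percentile target-box trigger logic with a
    non-triggered fallback, motor-evoked-potential quantification with
    quality control and interhemispheric-inhibition (IHI) ratios, corrected
    imaginary coherence connectivity with surrogate significance and a
    network-intensity summary, and the accompanying statistical battery
    (repeated-measures ANOVA with Greenhouse-Geisser correction, Bonferroni
    paired contrasts, repeated-measures correlation, jackknife correlation,
    proportion tests, mixed models, and paired-t sample-size search).  A
    seeded synthetic EEG/EMG generator with known ground truth stands in for
    human participants and stimulation hardware, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
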