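Package: cprsaa
Title: Rhythm Analysis During Cardiopulmonary Resuscitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ECG rhythm analysis during ongoing chest compressions. Suppresses
    the cardiopulmonary resuscitation (CPR) compression artifact with a
    harmonic least-mean-squares (LMS) adaptive filter driven by compression
    timing marks, then issues shock/no-shock advice on the filtered ECG with a
    two-stage shock advice algorithm: a low-electrical-activity detector
    followed by a Gaussian-kernel support vector machine on slope and spectral
    features. Decisions are made per 3-s window and per 9-s segment by
    majority vote. Includes seedable generators for coarse ventricular
    fibrillation, organized rhythms, asystole and compression artifacts, plus
    evaluation tools (sensitivity, specificity, balanced error rate, positive
    predictive value, AUC, record-level bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
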