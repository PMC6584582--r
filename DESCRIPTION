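Package: agonalert
Title: Contactless Detection of Agonal Breathing in Bedroom Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming audio pipeline for detecting agonal breathing, the
    gasping respirations that accompany roughly half of out-of-hospital
    cardiac arrests. Audio is normalized, resampled to 16 kHz and cut into
    2.5 second segments; each segment is transformed into a log-mel
    spectrogram, compressed to a 256-dimensional PCA embedding, and scored
    by a radial-basis-function support vector machine. A temporal
    plausibility filter converts per-segment detections into alarms only
    when detections recur at the physiologic agonal rate of 3-6 breaths per
    minute. The package also provides a Sign-Data LMS adaptive filter that
    cancels a device's own known playback before classification, FMCW chirp
    synchronization for over-the-air benchmark experiments, a seeded
    synthetic acoustic-scene generator (agonal gasp trains, snoring,
    hypopnea, apnea, household interference), and evaluation tools
    (ROC/AUC, Wald confidence intervals, streaming false-positive
    accounting, benchmark condition grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
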