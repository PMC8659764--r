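Package: sleepglove
Title: Overnight Sleep Monitoring Analytics for Smart-Glove PPG, SpO2 and
    Actigraphy Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computation stack for overnight recordings from a
    finger-worn pulse-oximeter glove: a bit-exact lossless block codec for the
    device's delta/Huffman binary format, photoplethysmography (PPG) pulse
    detection and per-minute heart-rate analytics (bradycardia, tachycardia,
    atrial-fibrillation- and premature-ventricular-contraction-like
    irregularity), breathing-rate estimation by fusing respiratory
    modulations of the PPG with a quality-weighted Kalman smoother,
    sleep-disordered-breathing analysis (decrease-in-amplitude-fluctuation
    event detection, SpO2 desaturation coupling, pulse-rate-variability
    feature extraction and Gaussian-kernel SVM subtype classification),
    accelerometer movement-count sleep staging, a seeded synthetic
    overnight-recording generator with ground-truth ledgers, and a pipeline
    that assembles the per-minute and whole-night report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    stats,
    e1071,
    pROC
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
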