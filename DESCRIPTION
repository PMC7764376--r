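Package: ppgresp
Title: Breathing Metrics from Photoplethysmography by Sequence Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates paired finger photoplethysmogram (PPG) and relative
    tidal-volume recordings in which breathing modulates pulse amplitude,
    baseline and beat interval; trains LSTM and one-dimensional U-Net
    sequence regressors that map 320-sample PPG windows to a relative
    tidal-volume waveform; segments the waveform into breaths to derive
    inspiration time, expiration time, inspiratory:expiratory ratio,
    inter-breath interval and breathing rate; and evaluates agreement
    against a reference volume trace with Pearson correlation, paired
    t-tests and Bland-Altman limits of agreement under blocked k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
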