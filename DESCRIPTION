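Package: neovitals
Title: Camera-Based Non-Contact Vital-Sign Estimation for Neonatal Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating heart rate and respiratory rate from video
    of preterm infants without skin contact. Extracts photoplethysmographic
    imaging (PPGi) signals by spatially averaging colour channels over
    segmented skin regions, detects cardiac pulses with a slope-sum
    transform, estimates heart rate by beat counting, FFT, and
    autoregressive dominant-pole methods, and fuses per-second estimates
    with signal-quality-weighted Kalman filters. Twelve respiratory channels
    are derived from PPGi colour signals, skin-region shape properties and
    moment-matched ellipse fits, with two independent breath detectors and
    multi-channel Kalman fusion. Includes baseline colour-model skin
    classifiers, the segmentation/detection loss and overlap metrics used to
    train skin-segmentation networks, gold-standard reference construction
    from ECG/PPG/impedance-pneumography monitor waveforms, evaluation
    statistics (MAE, MAD, Bland-Altman, gap analysis), and a synthetic scene
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mclust,
    signal,
    stats,
    utils,
    zoo
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
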