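Package: abpwave
Title: Arterial Blood Pressure Waveform Imaging, Classification and
    Notch-Centered Feature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for continuous intraoperative arterial
    blood pressure (ABP) waveforms: synthetic cohort generation with
    ground-truth beat landmarks, zero-phase detrending and rule-based pulse
    segmentation with two-detector reconciliation, construction of
    normalized multi-pulse instances, five signal-to-image encodings
    (Gramian angular summation field, Markov transition field, recurrence
    plot, spectrogram, direct raw pulse plotting), a compact convolutional
    classifier with patient-level splits, class-weighted loss, early
    stopping and Grad-CAM saliency, instance-to-patient aggregation
    (mean/majority voting and top-k pooling) with AUROC evaluation and
    conventional machine-learning baselines, and a notch-centered
    three-segment derivative-statistic feature battery with IQR outlier
    filtering and normality-gated two-group testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    signal,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
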