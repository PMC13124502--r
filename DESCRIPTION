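Package: emofuse
Title: Multimodal Physiological Emotion Recognition with PCA-LSTM Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for three-class emotion recognition
    (positive, neutral, negative) from synchronized prefrontal EEG, ECG and
    galvanic skin response recordings. Provides a synthetic-data generator
    that emulates emotion-conditioned physiological structure with known
    ground truth; modality-specific preprocessing (average-referenced and
    notch-filtered EEG with amplitude-threshold artifact rejection,
    Pan-Tompkins R-peak detection with ectopic-beat interpolation,
    low-passed and within-participant Z-scored skin conductance); extraction
    of eleven trial features (frontal alpha asymmetry indices by wavelet
    packet decomposition, time/frequency/nonlinear heart-rate-variability
    indices, tonic skin conductance level and non-specific response counts);
    repeated-measures ANOVA feature screening with Greenhouse-Geisser
    correction and Tukey HSD post-hoc tests; and a PCA-LSTM classifier with
    classical baselines evaluated under leakage-free nested stratified
    five-fold cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
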