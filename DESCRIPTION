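Package: vfdetect
Title: Shock Decision Algorithms for Lethal Ventricular Arrhythmia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end shock/no-shock decision algorithms for automated
    external defibrillators (AEDs). Implements AED-style ECG conditioning
    (mean subtraction, moving average, 1-30 Hz bandpass), rhythm-segment
    extraction with clinical exclusion rules (asystole, fine VF, slow VT,
    noise), patient-wise data partitioning, a mixed 1D-convolutional plus
    long short-term memory (CNN+LSTM) classifier trained with class-weighted
    cross-entropy and balanced-accuracy threshold selection, CNN-only and
    Gaussian-kernel SVM baselines with Bayesian hyperparameter search, and a
    full evaluation suite (sensitivity/specificity/balanced accuracy, McNemar
    paired comparison, per-feature ROC-AUC ranking, t-SNE plus Davies-Bouldin
    separability, AHA compliance checks). A built-in generator produces
    patient-structured synthetic ECG cohorts so every stage is exercisable
    without downloading clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    MASS,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
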