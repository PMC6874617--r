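Package: ieegactive
Title: Unsupervised Classification of Task-Active Intracranial EEG Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fully automated, unsupervised identification of intracranial EEG
    electrodes that respond to a cognitive task. Event-locked epochs are
    converted to z-scored, trial-averaged spectrograms; three interpretable
    spectral metrics (induced power, smoothness score, gamma consistency)
    summarise each electrode; and a two-component Gaussian mixture model,
    with the smaller mixture component designated active, classifies
    electrodes pooled across subjects. Includes bipolar montage construction,
    resampling and epoching of raw recordings, a standard-deviation
    thresholding baseline, principal-component analysis of the metric space,
    sensitivity/specificity/AUC evaluation with leave-one-subject-out
    cross-validation, anatomical region summaries, and a synthetic-signal
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
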