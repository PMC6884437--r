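Package: infoload
Title: Information-Theoretic Cognitive-Load Estimation from Prefrontal NIRS Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the cognitive load expressed in prefrontal-cortex
    near-infrared spectroscopy (NIRS) recordings as the conditional entropy
    of windowed task-period activity given a resting baseline, with a
    mutual-information / Kullback-Leibler gated update rule that damps
    short-lived signal fluctuations.  Provides the full analysis chain:
    session I/O for multi-channel NIRS time series, bandpass filtering,
    linear detrending and rest-period PCA attenuation of skin blood flow,
    histogram estimators of entropy, mutual information, KL divergence and
    variation of information, a decision-boundary fit separating two
    cognitive-load populations, easy/difficult classification of session
    medians, evaluation statistics (confusion metrics, rank tests and
    bootstrap procedures), and a seeded synthetic NIRS session generator
    for end-to-end validation without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
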