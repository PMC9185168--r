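Package: brada
Title: Brain-Region-Aware Kernel Domain Adaptation for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject and cross-database EEG emotion
    recognition with brain-region-aware kernel domain adaptation. Implements
    region-based channel selection on the 32-electrode 10-20 montage,
    differential-entropy and Welch power-spectral-density band features with
    joint min-max normalization, maximum-independence subspace learning via
    the Hilbert-Schmidt independence criterion with domain-feature
    augmentation, transfer-component-analysis and subspace-alignment
    baselines, SVM evaluation under leave-one-subject-out and cross-database
    protocols, subspace-dimension search, ablation suites, and a synthetic
    multi-subject affective-EEG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
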