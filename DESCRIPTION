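Package: ecgfusion
Title: Multimodal Transformer Fusion for 12-Lead ECG Multilabel Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A query-conditioned multimodal transformer for 13-category
    multilabel cardiovascular diagnosis from 12-lead electrocardiograms.
    Structured machine-measured ECG features (interval timings, electrical
    axes) form an attention query that retrieves relevant waveform patch
    context before transformer encoding; demographics enter as metadata
    tokens. Includes a seeded synthetic ECG cohort generator with plantable,
    time-localised pathology signatures, deterministic preprocessing and
    chronological/random dataset splitting, a class-imbalance-aware weighted
    binary cross-entropy training loop with plateau learning-rate decay and
    early stopping, macro-averaged multilabel evaluation with Platt
    calibration and demographic subgroup reports, and cross-attention
    heatmap export for interpretability. The network, its backpropagation
    and the optimiser are implemented in vectorised base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
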