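Package: sleepsiam
Title: Siamese-Network Sleep Staging from Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic sleep-stage classification (W, N1, N2, N3, REM) from
    30-second single-channel EEG epochs using Siamese encoders with a shared
    parameter set. Two encoder variants are provided: a two-branch
    convolutional network and a convolutional autoencoder. Training combines
    a margin-based contrastive loss over epoch pairs, multi-class
    cross-entropy, and (for the autoencoder) a reconstruction distance that
    sums a Euclidean term and the max-sliced Wasserstein-2 distance. The
    package includes a two-stage pretrain/finetune protocol with per-block
    learning rates, subject-wise k-fold cross-validation, the full evaluation
    suite (per-class precision/recall/F1, accuracy, macro-F1, Cohen's kappa
    from summed confusion matrices), and a stage-conditioned synthetic EEG
    generator so the whole pipeline runs without any recorded data. All
    network layers and their gradients are implemented in vectorised base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
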