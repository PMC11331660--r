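Package: cardiocl
Title: Continual-Learning Method Selection for Multicenter ECG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training an arrhythmia detector across multiple
    institutions that cannot share raw records. Implements three
    regularization-based continual-learning candidates (knowledge
    distillation, elastic weight consolidation, and memory-aware synapses),
    an on-line method-selection algorithm that scores candidates on
    GAN-synthesized surrogate data with continual hyperparameter decay, a
    WGAN-GP waveform synthesizer with privacy-oriented random demographic
    pairing, and supervised, federated (FedAvg/FedProx), and finetuning
    baselines. Includes a residual 1D-convolutional detector, a desk-scale
    simulator of heterogeneous multicenter 12-lead ECG-like datasets, a
    non-IID site splitter, and rank-based AUROC metrics. All neural-network
    training runs on a small reverse-mode engine written in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pROC,
    pracma
Config/testthat/edition: 3
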