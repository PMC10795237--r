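Package: mscan
Title: Multi-Scale Self- and Cross-Attention Networks for RNA
    Methylation Site Prediction
Version: 0.1.0
Authors@R:
    person("MSCAN", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Predicts RNA modification (methylation) sites from fixed
    41-nucleotide sequence windows with a multi-scale transformer
    encoder.  Windows are tokenized into overlapping 3-mers, embedded
    with a CBOW word-embedding model trained on the input corpus, and
    classified by an encoder that fuses self-attention on a query scale
    with cross-attention toward two centred sub-windows of different
    lengths.  The package provides the four ablation variants of the
    encoder (SAN, SCAN, MCAN, CAN), mini-batch Adam training with
    binary cross-entropy, threshold and ranking metrics (sensitivity,
    specificity, accuracy, precision, F1, MCC, AUROC, AUPRC), replicated
    t-test model comparison, a cross-modification validation matrix, and
    a synthetic motif-window generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
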