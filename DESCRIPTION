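Package: mmcoder
Title: Multimodal Case-Record Coding with Causal and Constrained Cross-Modal Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transformer-style architecture for automated coding of multimodal
    clinical case records (image, text, structured features): causal masked
    self-attention encoders, allowed-pair constrained cross-modal attention
    fusion, low-rank (LoRA) adaptation, and a weighted multi-task objective
    with auxiliary contrastive-alignment and severity-prediction tasks.
    Includes the standard multi-label evaluation metrics (subset accuracy,
    macro F1, macro AUC-ROC, Jaccard index, Hamming loss), a seeded synthetic
    multimodal case generator with noise and data-reduction perturbations, and
    a training/ablation/robustness harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
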