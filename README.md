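# mmcoder

Automated coding of multimodal clinical case records — image, text and
structured features jointly — with a transformer-style architecture built
from three mechanisms:

* **Causal masked self-attention**: within each modality, token *i* attends
  only to tokens *j ≤ i* via an additive mask (0 for *i ≥ j*, −∞ for
  *i < j*) inside `softmax(QKᵀ/√d_k + M)V`; masked positions receive
  exactly zero weight.
* **Allowed-pair constrained cross-modal fusion**: cross-modal attention is
  restricted to a whitelist *P* of ordered (query-modality, key-modality)
  pairs, computed as `LayerNorm(X_q + Concat(head_1..head_h)W_O)` plus a
  position-wise feed-forward `W₂ ReLU(W₁x + b₁) + b₂`, so modalities
  interact only along declared channels.
* **LoRA + multi-task learning**: a frozen base weight *W₀* with a
  trainable rank-*r* update *ΔW = BA* (`h = W₀x + B(Ax)`, mergeable as
  *W₀ + BA*), trained under the joint objective Σₖ λₖLₖ combining the
  primary coding loss with two auxiliary tasks — symmetric InfoNCE
  contrastive alignment across the modalities of a case, and 3-level
  severity prediction.

The package ships the five standard multi-label metrics (subset accuracy,
macro F1, macro one-vs-rest AUC-ROC with midrank ties, sample-averaged
Jaccard index, Hamming loss), the relative-change/absolute-drop comparison
arithmetic, a seeded synthetic multimodal case generator with input-noise
and reduced-data perturbations, a training harness with early stopping, a
robustness/ablation runner, and a CLI (`exec/mmcoder`).

Audience: researchers prototyping structured multimodal fusion /
parameter-efficient adaptation methods at desk scale, and anyone needing a
fully tested, dependency-light reference implementation of these blocks in
R.

## Worked example

```r
library(mmcoder)

ds  <- generate_dataset(generator_config(seed = 11))  # 600 cases, 3 classes
mod <- build_model(model_config(), n_classes = 3, structured_dim = 8, seed = 1)
fit <- train_model(mod, ds, train_config(seed = 1, verbose = TRUE))
evaluate_model(fit$model, ds, split = "test")
```

```
epoch 1 | loss 2.4833 | val subset acc 0.6667
epoch 2 | loss 1.7499 | val subset acc 1.0000
...
epoch 7 | loss 1.0685 | val subset acc 1.0000
<metrics_report>
Subset Accuracy(%)        Macro F1(%)      Macro AUC-ROC   Jaccard Index(%)
               100                100                100                100
   Hamming Loss(%)
                 0
  (hamming loss as fraction: 0)
```

Training stops early once validation subset accuracy stops improving
(patience 5) and restores the best epoch. At the generator's default class
separation (δ = 4) the three synthetic classes are nearly separable, so a
correctly wired model drives all five metrics to their optimum on the test
split — the interesting comparisons are the *relative* ones below.

Robustness and ablation:

```r
rob <- run_robustness(model_config(), train_config(seed = 1), ds, seeds = 1:3)
rob$drops        # percent-point drop per metric under +20% noise / -30% data
ab  <- run_ablation(model_config(), train_config(seed = 1), ds)
ab$relative      # relative change vs the full model per removed module
```

Comparison arithmetic (one convention for improvements and ablation drops):

```r
relative_change(49.0, 55.2)  # 12.7  (baseline 49.0 -> model 55.2, percent)
absolute_drop(64.8, 63.2)    # 1.6   (percent-point robustness drop)
```

## Command line

```sh
exec/mmcoder simulate --seed 1 --out-dir out        # write JSONL fixtures
exec/mmcoder train --fixtures out/fixtures --out-dir out
exec/mmcoder robustness --seed 1 --out-dir out
exec/mmcoder ablate --seed 1 --out-dir out
exec/mmcoder report --rows out/robustness.csv --out-dir out
```

Config files (`--config`, YAML or JSON) may hold any
`model_config`/`train_config`/`generator_config` field, including the
allowed-pair policy as a list of `[query, key]` modality pairs.

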