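---
title: "Multimodal case-record coding: model, objective and evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal case-record coding: model, objective and evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Automated coding of clinical case records is a multi-label classification
problem over heterogeneous inputs: a medical image, a text note, and a vector
of structured indicators all describe the same case, and the coding decision
should draw on all three. `mmcoder` implements a transformer-style
architecture for this setting built from three mechanisms:

1. **Causal masked self-attention.** Within each modality, token $i$ may
   attend only to tokens $j \le i$. The additive mask $M$ has $M_{ij} = 0$
   for $i \ge j$ and $-\infty$ for $i < j$, applied inside the softmax of
   scaled dot-product attention,
   $Z = \mathrm{softmax}(QK^\top/\sqrt{d_k} + M)\,V$, so future positions
   receive *exactly* zero weight — not merely a small one. This is a
   contract we test, which is why masking is implemented by renormalizing
   over visible entries rather than by adding a large negative constant.
2. **Allowed-pair constrained cross-modal attention.** Fusion attention is
   restricted to a whitelist $P$ of ordered (query-modality, key-modality)
   pairs. Entry $(i,j)$ of the fusion mask is visible iff
   $(\mathrm{mod}(i), \mathrm{mod}(j)) \in P$. The block computes
   $\mathrm{LayerNorm}(X_q + \mathrm{Concat}(\mathrm{head}_1..\mathrm{head}_h)W_O)$
   followed by a position-wise feed-forward sub-layer
   $W_2\,\mathrm{ReLU}(W_1 x + b_1) + b_2$.
3. **LoRA + multi-task learning.** A frozen base weight $W_0$ carries a
   trainable rank-$r$ update $\Delta W = BA$ ($B$ zero-initialized, so the
   adapted model equals the base model at the start); the training objective
   is the weighted sum $\sum_k \lambda_k L_k$ over the primary coding loss
   and two auxiliary tasks: symmetric InfoNCE contrastive alignment of the
   per-modality case embeddings, and 3-class severity prediction
   (mild/moderate/severe).

Evaluation uses the five standard multi-label metrics — subset accuracy,
macro F1, macro one-vs-rest AUC-ROC, Jaccard index, Hamming loss — plus the
relative-change and absolute-drop arithmetic used in comparison, robustness
and ablation tables.

# Architecture and wiring choices

Several wiring details are genuinely open design choices; the package fixes
them as follows and exposes the rest through `model_config()`:

* **Token order.** A causal mask needs a total order. Case records are
  assembled in the canonical order *structured → text → image patches*, each
  modality in its natural internal order, with fixed sinusoidal positional
  encodings added at assembly. The intended sequential axis of causality in
  single-time-point records is ambiguous; we implement token-order causality
  and treat the mask as an information-flow regularizer.
* **Block wiring.** The causal encoder blocks are *pre-norm* residual blocks
  (LayerNorm → attention → add → LayerNorm → feed-forward → add), the
  stable choice at small scale. The fusion block is *post-norm* exactly as
  its defining equation is written
  ($\mathrm{LayerNorm}$ outside the residual sum), with the feed-forward
  applied as a second residual + LayerNorm sub-layer.
* **Causal-then-fuse.** Each modality is encoded by the (shared-weight)
  causal stack separately; the encoded sequences are then concatenated and
  fused by one allowed-pair-constrained self-attention block over the joint
  sequence. With the default policy
  $P = \{(\mathrm{text},\mathrm{image}), (\mathrm{image},\mathrm{text}),
  (\mathrm{structured},\mathrm{text}),
  (\mathrm{structured},\mathrm{image})\}$ both directions of text↔image
  exchange plus structured read-out are realized inside the single block;
  this generalizes a two-block per-direction scheme to three modalities
  without extra parameters. The policy is configurable
  (`modality_policy()`).
* **Fully masked query rows.** A policy may leave a query modality with no
  allowed keys. Softmax over an empty visible set is defined as the zero
  vector, and such rows contribute a zero attention term (bias included), so
  the block degrades to $\mathrm{LayerNorm}(X_q)$ instead of producing NaN.
* **Pooling and heads.** Mean pooling over fused tokens feeds a linear
  coding head and a linear severity head. The contrastive task uses the
  *pre-fusion* per-modality mean pools — after fusion the views are mixed
  and alignment would be trivial.
* **LoRA placement.** Adapters attach to the query and value projections of
  every attention block, rank 4 by default, exactly $\Delta W = BA$ with no
  $\alpha/r$ scaling (any scaling is absorbed by the learning rate). The
  package supports both full fine-tuning (default) and adapter-only
  training with frozen base q/v weights (`lora_enabled = TRUE`).

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d_model` | 64 | embedding width (= heads × head dim) |
| `n_heads` | 4 | attention heads per block |
| `n_causal_blocks` | 2 | causal encoder depth per modality |
| `ffn_hidden` | 128 | feed-forward hidden width |
| `lambda_*` | 1 / 0.3 / 0.3 | coding / contrastive / severity loss weights |
| `tau` | 0.1 | contrastive temperature |
| `lora_rank` | 4 | adapter rank |
| `lr`, `batch_size` | 1e-3, 32 | Adam step size, mini-batch size |
| `epochs`, `patience` | ≤ 40, 5 | budget and early-stopping patience |

Early stopping monitors validation subset accuracy and restores the
best-epoch parameters. Training is fully deterministic given the seeds
(single-threaded contract): parameter initialization derives from the
model-build seed, shuffling and every stochastic step from the training
seed.

# The synthetic case generator

Real radiography/medical-image benchmark datasets are deliberately out of
scope; the generator emulates their *shape* so every mechanism is testable
without downloads. Per record of class $c$ (of $C = 3$, near-uniform):

* structured features $\sim \mathcal N(\mu_c, I)$ in $d_s = 8$ dimensions,
  with all pairwise class-mean distances equal to the separation
  $\delta = 4$;
* a $16 \times 16$ image = class template (stripes / quadrant / checker
  patterns) + $\mathcal N(0, 0.1)$ pixel noise, clipped to $[0,1]$;
* 12 text tokens from a vocabulary of 32, with 60% of the probability mass
  on a class-specific vocabulary block;
* a one-hot label vector, and a severity label from tercile bins of the
  latent deviation $\lVert x - \mu_c \rVert$.

Defaults ($n = 600$, 70/15/15 stratified splits) were chosen once as a
desk-scale configuration a CPU trains in well under a minute; at
$\delta = 4$ the classes are nearly separable, which is intentional: the
end-to-end checks assert that the full pipeline *can* recover near-perfect
structure, and the ablation checks compare variants under identical
conditions. What passing these tests does **not** show: performance on real
clinical data, realistic image statistics, clinical text semantics, label
co-occurrence structure (the generator is single-label rendered as one-hot
multi-label), or class imbalance.

Two perturbations mirror the robustness protocol:

* `apply_input_noise(fraction = 0.2)` corrupts exactly
  $\lfloor 0.2 \cdot \text{total entries} \rfloor$ feature entries, pooled
  across all structured coordinates and image pixels and chosen uniformly,
  with additive Gaussian noise at one empirical standard deviation. The SD
  is computed per field kind (structured vs pixels) because the two live on
  different scales; pixels are re-clipped to $[0,1]$ and any entry that
  clips back onto its original value has its noise redrawn so the
  corrupted-entry count contract is exact. A label-noise variant is a
  possible alternative reading of "input noise"; feature corruption is
  implemented because the robustness claim concerns noisy *inputs*.
* `subsample_training(keep = 0.7)` drops 30% of the *training* records
  only. Incomplete records (missing modalities) are exercised separately by
  `drop_modality()`; absent modalities contribute zero tokens and the
  masks adapt.

# Numerical choices

* Softmax is computed with per-row max subtraction over visible entries;
  fully masked rows return zeros.
* The AUC estimator is the Mann–Whitney rank statistic with midrank tie
  handling; label columns with a single class are excluded from the macro
  average (an error only if all are).
* Zero-denominator conventions: precision, recall, F1 and per-sample
  Jaccard are 0 when their denominator is 0, except the all-empty-union
  Jaccard, which is 1 (truth and prediction agree on "nothing"). The
  Jaccard metric averages per *sample* as its defining formula does; a
  per-label averaging variant is available via
  `jaccard_index(average = "labels")`.
* `relative_change()` is $100\,|new - ref|/ref$ with half-up rounding to
  one decimal — the single convention that reproduces both
  baseline-improvement and ablation-decrease arithmetic; `absolute_drop()`
  is the percent-point difference used in robustness rows.
* Gradients are exact reverse-mode derivatives of every layer (attention,
  layer norm, feed-forward, LoRA factors, InfoNCE, both heads), verified
  against central finite differences in the test suite.
* Severity is treated as plain 3-class classification, not ordinal
  regression.

# Problem sizes used by the checks

The test suite and acceptance script run at the generator defaults
($n = 600$): one standard training run per seed, the three robustness
settings over three seeds, and the three single-module ablations. These
sizes were fixed as the package's desk-scale study conditions. The metric
implementations are additionally checked against exhaustive
from-definition enumeration over all binary truth/prediction pairs for
shapes up to $N \times L \le 6$ (4,096 pairs per shape) plus a seeded
4,096-pair sample of the $3\times3$ space, and against an independent
reference implementation on 1,000 random instances.

# Known limitations

* The coding loss defaults to softmax cross-entropy over mutually exclusive
  classes (matching the generator); true multi-label data needs
  `multilabel = TRUE` (element-wise binary cross-entropy), which the
  synthetic study does not exercise end-to-end.
* The causality contract applies to the per-modality causal encoder stage;
  after cross-modal fusion, representations intentionally mix modalities.
* The allowed-pair set for real deployments is domain knowledge the user
  must supply; the default is a reasonable symmetric text↔image policy with
  structured read-out, not a learned quantity.
* No GPU or multi-threaded path; the implementation targets correctness and
  desk-scale reproducibility, not throughput.
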