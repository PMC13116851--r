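---
title: "Minimal diagnostic view selection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal diagnostic view selection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseviews)
```

## The problem

Routine identification of insect disease vectors (flies, mosquitoes) from
pinned specimens photographs a fixed set of standardized anatomical views
per specimen — mesonotum, hypopleura, basicosta, wings, and so on. Two
practical questions arise. First, does fusing all views beat the best
single view? Second, since every encoded view costs a full backbone
forward pass, which *minimal* subset of views preserves identification
accuracy? `sparseviews` answers both with a single differentiable
mechanism: each view passes through a stochastic Hard-Concrete gate, an
expected-L0 penalty on the open gates competes with the classification
loss, and sweeping the penalty weight traces the accuracy/compute Pareto
frontier from which a margin rule picks the recommended subset.

## Model

Each view image (or feature vector) $x_i$ is encoded by a single
shared-weight encoder into an embedding $v_i \in \mathbb{R}^D$; spatial
positions are aggregated by learnable-query cross-attention pooling. A
learnable view-specific positional encoding is added,

$$e_i = v_i + PE_i,$$

and the tokens are fused by one multi-head self-attention block (8 heads,
residual attention and feed-forward sublayers) followed by mean pooling
over active tokens and a linear softmax classifier.

Between encoding and fusion sits the gate. For view $i$ with learnable
logit $\alpha_i$ and temperature $\beta$, a gate value is sampled by the
reparameterization

$$z_i = \mathrm{clip}\!\left(\sigma\!\left(\tfrac{\log u - \log(1-u) +
\alpha_i}{\beta}\right)(\zeta - \gamma) + \gamma,\; 0,\; 1\right),
\qquad u \sim U(0,1),$$

with stretch parameters $\zeta = 1.1$, $\gamma = -0.1$. The stretched,
clipped distribution places positive mass at exactly 0 and exactly 1, so
sampled gates can switch views fully off while remaining differentiable
in $\alpha_i$ elsewhere. The gated token is $z_i \odot e_i$. The expected
number of open gates has the closed form

$$L_{L0} = \sum_{i=1}^{N} \sigma\!\left(\alpha_i - \beta
\log\tfrac{-\gamma}{\zeta}\right),$$

which is the differentiable sparsity penalty. The training objective is

$$L_\text{total} = L_\text{CE} + \lambda_\text{contrast}
L_\text{contrast} + \lambda_\text{sparsity} L_{L0},$$

with cross-entropy, a supervised contrastive term
($\lambda_\text{contrast} = 0.2$, temperature $\tau = 0.1$, cosine
similarities of the L2-normalized projected fused representation) that
sharpens the separation of sibling species, and the sparsity term whose
weight is the sweep variable. The temperature $\beta$ anneals linearly
from 0.67 to 0.1 over training, hardening the gates as learning
progresses.

At test time gating is deterministic: view $i$ is retained iff its
retention probability $P(z_i > 0) = \sigma(\alpha_i - \beta
\log(-\gamma/\zeta))$ exceeds a threshold (0.5 by default), retained
gates are set to exactly 1, and dropped views are not encoded at all.
That last convention is what makes theoretical cost exactly linear in
the retained view count, so a sweep table's FLOPs column is
`view_count * per_view_flops`.

## The sweep and the margin rule

`run_sweep()` trains one gated model per $\lambda_\text{sparsity}$ in a
grid (default $\{0.1, \dots, 0.5\}$, each from a fresh initialization
under the same seed policy) plus a $\lambda = 0$ all-view baseline, and
records retained views, Top-1 validation accuracy under the
deterministic mask, and FLOPs. `select_recommended()` implements the
margin rule: among records whose accuracy drop from the all-view
baseline is at most 1 percentage point, pick the fewest-view record
(ties: lower FLOPs, then lower $\lambda$); if nothing qualifies, the
baseline itself is returned. `label_configurations()` names rows
all-view / reduced / recommended / aggressive / single-view, in the
sense used by the sweep tables this package exports.

Margin semantics: "within 1%" is interpreted as 1.0 percentage point of
Top-1 accuracy, i.e. a difference of printed percentages, not a relative
ratio — a drop of 0.93 pp qualifies, 2.78 pp does not.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `zeta`, `gamma` | 1.1, −0.1 | stretch interval of the Hard-Concrete gate; must straddle [0,1] for exact boundary mass |
| `beta_start`, `beta_end` | 0.67, 0.1 | concrete temperature annealing endpoints |
| `selection_threshold` | 0.5 | retention-probability cutoff of the deterministic mask |
| `lambda_contrast`, `tau` | 0.2, 0.1 | weight and temperature of the supervised contrastive term |
| `lambda_sparsity` | sweep variable | price of a retained view, in loss units per expected open gate |
| `margin_pp` | 1.0 | accuracy-drop margin of the recommendation rule |
| `lr`, `weight_decay` | 1e-6, 5e-3 | AdamW settings of the production recipe (pretrained backbone) |

Annealing shape is linear in epoch: the endpoints are fixed by the
recipe, the path between them is not; linear is the simplest monotone
choice and is exposed in `gate_config()` should a different schedule be
wanted. The selection threshold of 0.5 is the natural majority cutoff
on a probability; converged gates sit near 0 or 1, so the exact value
is uncritical.

## The reference-tiny model and desk-scale training

Production systems put a pretrained convolutional backbone behind the
encoder contract. This package ships `"reference-tiny"`: a linear patch
stem with tanh nonlinearity plus query pooling, randomly initialized,
with every gradient written analytically and verified against finite
differences in the test suite. It exists so that the full method —
gates, fusion, sweep, selection — runs end to end on one CPU in
minutes, which is also why all training-dependent tests use it.

Because it trains from random initialization, the reference model does
not use the production fine-tuning rate. `desk_train_config()` fixes
the desk-scale recipe: AdamW at learning rate 0.02 (same decoupled
weight decay 5e-3), batch size 48 with a class-balanced sampler (the
contrastive term needs in-batch positives; the sampler deals specimens
class-round-robin so any batch of at least twice the class count
contains them), 100 fusion epochs, cosine annealing with one warm
restart at epoch 50. Gate noise is drawn once per view per forward
pass. Gate logits initialize at $\alpha = 1$ (retention probability
0.93 at $\beta = 0.67$): selection should start from "views are
useful" and prune, not the reverse.

Two-stage training mirrors the production protocol: optional
single-view pretraining (`train_single_view()`, shared encoder + one
linear head per view) both provides the per-view accuracy table — whose
maximum is the single-view baseline — and can warm-start
`train_fusion()`. Stage 2 fine-tunes everything, including the encoder;
nothing is frozen.

## The synthetic data generator

`synthetic_spec()` emulates the structure of a real multi-view
collection: `C` species times `V` named views per specimen, class
signal planted only in a known subset `S`, nuisance variation
elsewhere. The default test geometry is `C = 6`, `V = 8`, `|S| = 3`,
signal strength 3, noise sd 1, 240 training and 60 validation
specimens — an 8-view fly-collection shape at desk scale.

The feature-mode class means are deliberately *complementary* rather
than redundant. Classes are partitioned into `|S|` groups; every
informative view carries a shared group-level direction (norm =
`signal_strength`), and the within-group contrast of group `k` — think
of a sibling-species pair separable only on one anatomical structure —
is carried by the `k`-th informative view alone (also norm
`signal_strength`; `redundancy_rho` leaks it into the other informative
views, 0 by default). Consequences, both verified in tests: classifying
from `S` alone achieves the same optimal accuracy as from all views
(Bayes sufficiency), and dropping *any* single informative view costs
real accuracy (the group's pair collapses to a coin flip). That second
property is what makes the margin rule identify exactly `S`: a sweep
point that prunes an informative view loses several percentage points
and cannot qualify.

What the generator does not emulate: photographic nuisances
(illumination, pose, occlusion), label noise, class imbalance beyond
rounding, and any correlation between specimens. Passing the planted
recovery experiments therefore demonstrates that the gating mechanism
finds a minimal sufficient view subset under controlled conditions; it
does not certify accuracy on real photographed collections.

Image mode renders 64-by-64 class-coded geometric templates into
informative views and a class-independent texture elsewhere, and exists
chiefly to exercise the image pipeline (PNG IO, resizing, patching,
augmentation) and the manifest format end to end.

## Numerical choices and degenerate inputs

* Gate noise `u` is required to be strictly inside (0, 1); boundary
  values would make `logit(u)` infinite and are rejected.
* A sampled gate of exactly 0 removes the view from attention and
  pooling; its reparameterized derivative is 0 there (clipped region),
  so soft training and hard inference agree — asserted as the masking
  equivalence test.
* If every gate closes, the fused representation is undefined;
  `fuse()` errors, and the trainer scores such a configuration at the
  majority-class rate (a model with no views can only express the
  prior).
* Accuracies are reported in percent, rounded half-up to 2 decimals
  (base R's `round()` rounds half to even, which published tables do
  not).
* FLOPs columns round to the published 2 decimals; sweep tables built
  on micro-GFLOP desk encoders keep enough digits for the per-view
  cost to stay visible. Savings percentages are computed from the
  rounded FLOPs cells, which is the convention that reproduces a
  37.49% saving from an 11.31 G baseline and a 7.07 G configuration.
* `predict_topk()` breaks probability ties by class index (stable,
  reproducible reports).
* Cross-entropy clamps a zero true-class probability at 1e-12 with a
  message instead of returning infinity.
* The contrastive term skips anchors without in-batch positives
  (excluded from the mean, not counted as zero); a batch with no
  eligible anchors contributes 0.

## Open design points, resolved

* *Which representation feeds the contrastive loss*: the fused
  specimen-level vector through a projection head discarded at
  inference — the term's purpose (separating sibling species) concerns
  the specimen representation, not individual views.
* *Does the query-pooling head act per view or after fusion*: per view
  only; fusion sees already-pooled view embeddings.
* *Fused-token pooling*: mean over active output tokens, no class
  token — symmetric and mask-friendly.
* *Attention depth*: one encoder block, feed-forward ratio 4. The
  desk-scale task does not support deeper stacks, and the fusion cost
  is excluded from the FLOPs accounting anyway (the per-view encoder
  dominates in production, where the printed totals are exactly
  view-count multiples of the per-view cost).
* *Sweep grids are per-dataset configuration*: the default is
  $\{0.1,\dots,0.5\}$; published tables may include further points
  (e.g. 0.6, or a 0.00–0.25 grid) and the table reader accepts any
  grid.

## Problem sizes used by the test suite

The planted-recovery experiment runs the full sweep (5 lambdas + 1
baseline, 100 epochs each, every run warm-started from one shared
single-view pretraining of the encoder — the two-stage protocol) on the
default generator geometry over 10 seeds — about 9–10 minutes on one CPU; the fusion non-inferiority
check runs two-stage training over 5 seeds in about two minutes; the
Monte-Carlo validation of the gate closed forms draws 100,000 samples
per (alpha, beta) grid point. These sizes are the package's chosen
desk-scale study conditions: small enough to re-run routinely,
large enough that the selection behaviour, not sampling luck, decides
the outcomes.

## Known limitations

* The reference-tiny encoder is not a production backbone; absolute
  accuracies on real photographs require plugging one in behind the
  encoder contract.
* Gates are global per view, not instance-conditional; group-sparsity
  and straight-through variants are out of scope.
* Confidence scores are raw softmax outputs, uncalibrated.
* FLOPs accounting covers encoders only; fusion-layer cost (shared by
  all configurations) is excluded by design.
* With a validation set of 60 specimens the accuracy quantum is 1.67
  pp, so margin decisions near the 1 pp boundary carry inherent
  sampling noise; larger validation splits sharpen them.
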