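---
title: "ardnet: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ardnet: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardnet)
```

## The problem

Real-time monitoring of invasive fish (the motivating case is the
alligator gar, labeled `Atra-spa`) in wild waters has to cope with
turbid water, poor lighting and partial occlusion, on hardware where
model size and inference cost matter. `ardnet` implements a lightweight
single-stage anchor-based detector built around three mechanisms: an
*involution* operator that generates its filter kernels from the feature
map itself, a *dual-channel attention* block (channel then spatial), and
a *cross-neighborhood grid matching* rule that multiplies the number of
positive samples per target. Everything — including the CPU training
engine with analytic gradients — is implemented in this package, so the
whole pipeline is exercisable end-to-end on synthetic scenes without
external data or hardware.

## Box decoding and positive-sample assignment

Predictions live on three grids (strides 8, 16, 32) with three anchor
priors per cell; each anchor slot carries `5 + N` values
`(t_x, t_y, t_w, t_h, objectness, N class logits)`. Offsets are
normalized through the sigmoid to keep training stable:

$$b_x = 2\sigma(t_x) - 0.5 + c_x,\qquad
  b_w = p_w\,(2\sigma(t_w))^2,$$

and likewise for $b_y$, $b_h$. Two consequences shape everything else:
the center can move in the open interval $(c-0.5,\,c+1.5)$ around its
cell, and the size is bounded by **4 times** the anchor
($\sup (2\sigma)^2 = 4$). `decode_box()` implements the rule;
`match_targets()` exploits it: a ground-truth box is positive in its own
cell *plus* the horizontal and vertical neighbor cells its fractional
center offsets lean toward (offset $<0.5$ leans left/up, $>0.5$
right/down, exactly $0.5$ adds nothing — the tie-break keeps assignments
deterministic). Anchors are gated by the size-ratio filter
$\max(w/p_w, p_w/w, h/p_h, p_h/h) < 4$ rather than by max-IoU: an anchor
more than 4x away in either dimension is unreachable by the decoder, so
training on it could never fit the target. Scoring at inference is
$\sigma(\text{class})\cdot\sigma(\text{objectness})$, followed by
thresholding and class-wise greedy NMS (ties broken by larger area, then
lower index).

The nine default anchor sizes (10x13 ... 373x326, three per scale) are
expressed at a 640-pixel input; configs built for smaller inputs rescale
them proportionally (`scale_anchor_set()`), which keeps the anchors'
coverage of the synthetic targets' size distribution intact.

## The involution operator

Convolution shares one kernel across all pixels and differentiates
channels; involution inverts this: at every pixel a $K\times K$ kernel
is generated from that pixel's feature vector and shared by a group of
channels ($G$ groups in total). Generation is a bias-free two-matrix
bottleneck with batch normalization and ReLU in the middle,

$$\mu_{i,j} = W_1\,\mathrm{relu}(\mathrm{norm}(W_0\,X_{i,j})),\qquad
W_0\in\mathbb{R}^{C/r\times C},\;
W_1\in\mathbb{R}^{K^2G\times C/r},$$

so the parameter count $C\cdot C/r + (C/r)K^2G + 2C/r$ is independent of
the feature-map size and nearly independent of $K$ — which is why large
kernels ($K=7$ here) are affordable and why the operator pays off
exactly in the widest stages. With stride $>1$ kernels are generated
from the average-pooled input so the kernel grid matches the output
grid. The vectorized forward is verified in the tests against a literal
quadruple-loop oracle (`involution_apply_naive()`), and its backward
pass against finite differences.

Defaults $r = 4$ and $G = C/16$ follow the operator's published
formulation; together with $K = 7$ they are pinned by the parameter
calibration below.

## Dual-channel attention

`cbam_forward()` is the canonical two-stage form: global average- and
max-pooled channel descriptors pass through one shared bias-free
bottleneck MLP (reduction 16), are summed and squashed to per-channel
weights in $(0,1)$; the channel-refined map's per-pixel mean and max
across channels are stacked and convolved with a single 7x7 filter to
give the spatial weight map. Both stages only multiply, so the block is
a pointwise contraction — it can suppress but never amplify, and a
saturated block is the identity. The block sits on the deepest backbone
tap (the network's layer 10), where capturing long-range context is
cheapest.

## The backbone and head

`build_backbone()` assembles: Focus slicing (lossless 2x2
space-to-depth of the RGB input into 12 channels at half resolution —
"quarter spatial size" is read as quarter *area*, since 12 channels
force a 2x2 slice), four stride-2 convolution + cross-stage-partial
(BCSP1) stages over the nominal channel plan 64/128/256/512/1024,
spatial pyramid pooling (max-pool windows 1/5/9/13, concatenated and
fused 1x1), and a final CSP stage whose bottleneck core is the
involution operator. Each CSP block splits its input into a processed
path (1x1 conv + bottlenecks) and a shortcut path, concatenated and
fused — the cross-stage hierarchy that avoids duplicated gradient
computation. Activations are SiLU throughout; convolutions carry batch
normalization and no bias.

`build_head()` is a pyramid fusion network: attention on the deepest
tap, a top-down path (1x1 reduce, nearest upsample, concat, CSP block)
down to stride 8, then a bottom-up path (stride-2 3x3 conv, concat, CSP
block) back up. The two deep fusion blocks — the network's layers 20 and
23, nominal 512 and 1024 channels — use involution cores; the final
per-scale 1x1 prediction convolutions stay plain convolutions (replacing
those as well degrades accuracy; parameter sharing across few-channel
layers destroys channel diversity). An *involution gate* encodes that
empirical boundary: involution cores are refused, with a warning, at
any stage whose nominal width is below 512 channels unless an ablation
flag lifts the gate.

## Parameter calibration

The published counts for this architecture — final backbone stage 4.1 M
with a convolution core vs 1.8 M with the involution core, involution
backbone 10.1 M, convolution-twin backbone 12.4 M — jointly pin the
configuration that is otherwise free. `scripts/calibrate.R` searches
width multipliers, bottleneck repeats and involution geometry; the
minimal solution (and the package default) is width 0.75, backbone
repeats (1, 3, 7, 2) (base plan (3, 9, 21, 6) at depth multiple 1/3),
K = 7, r = 4, G = C/16. The four counts are matched simultaneously by
this single configuration, which is strong evidence the interpretation
is right; the counts are asserted in the test suite and two of them are
recomputed by `scripts/acceptance.R`. The counts scope the *backbone*:
the difference between the involution and convolution backbone totals
equals the final-stage core swap almost exactly, which a full-detector
reading cannot reproduce.

## The composite loss

Training minimizes classification + localization + confidence:
binary cross-entropy on class logits over positives, the complete-IoU
(CIoU) loss on decoded boxes, and BCE objectness over all anchors with
the no-object term weighted by $\neg\alpha_{obj}$. The IoU family is
implemented in full (`iou`, `giou`, `diou_loss`, `ciou_loss`), with the
standard aspect-ratio term
$v = \tfrac{4}{\pi^2}(\arctan\tfrac{w_{gt}}{h_{gt}} -
\arctan\tfrac{w}{h})^2$, $\alpha = v/((1-IoU)+v)$ — the source leaves
$v$ and $\alpha$ undefined, so the standard published form is adopted
and documented as an assumption. The analytic gradient of the CIoU loss
(including $\alpha$'s dependence on IoU and $v$) is differentiated by
hand and checked against finite differences.

Values the source does not pin down are exposed in `loss_config()` with
lineage defaults: $\neg\alpha_{obj} = 0.5$, term weights
(class, loc, conf) = (0.5, 0.05, 1), per-scale objectness balance
(4, 1, 0.4), and per-term mean reduction. A strict mode
(`loss_config_strict()`) reproduces the published unweighted raw-sum
form. Two objectness-target modes exist: the default soft label (the
detached CIoU of the decoded box, coupling confidence to localization
quality) and the hard indicator label. The hard label is what the
published loss writes, and it is the right mode for overfit sanity
checks: a soft label $t\in(0,1)$ leaves an irreducible entropy floor
$-t\log t-(1-t)\log(1-t)$ in the BCE, so the total loss cannot approach
zero no matter how well the network fits.

## Training engine

There is no automatic differentiation: every layer implements an
explicit backward pass (im2col convolution and the involution
application in C++ via RcppArmadillo, batch norm / SiLU / attention /
plumbing in R), and the whole chain is verified end-to-end against
finite differences in the tests. The optimizer is Adam at constant
learning rate 0.001 with first-moment decay 0.6 — the training
protocol's "momentum 0.6" is interpreted as Adam's $\beta_1$ — batch
size 16 by default, no warmup or decay (a cosine schedule is available
behind a flag). Batch normalization uses batch statistics in training
and running statistics (momentum 0.1) at inference; eval-mode forward
passes free intermediates eagerly to keep memory flat.

## Synthetic scenes

`generate_scene()` emulates the *statistical structure* of a
field-collected monitoring dataset: a bluish-green, unevenly lit,
low-frequency-textured background; elongated fish-like targets (rotated
ellipse body plus tail lobe, stripe texture, mostly horizontal
orientations); exactly one target in 73% of scenes and 2-4 otherwise;
occasional dark occluder strips; and photometric degradations
(low-light gain, Gaussian noise, blur) as separate operators that leave
boxes untouched. Target box areas are log-uniform between 0.2% and 30%
of the image so all three pyramid scales receive positives. Every box
is the exact bounding box of the drawn mask, so annotations are tight
by construction. Each scene is generated under its own derived seed and
is byte-reproducible; dataset manifests record the per-scene seeds.

What the generator does *not* model: photorealistic water optics,
realistic fish appearance, background objects that mimic fish texture,
or annotation noise. Passing tests on these scenes therefore
demonstrate that the architecture, assignment, loss and optimizer are
implemented correctly and can learn a detection task end-to-end — they
do not certify accuracy on real underwater imagery.

## Problem sizes and numerical choices

The test suite runs entirely on CPU at sizes chosen to exercise every
mechanism while staying quick: the oracle and property tests use feature
maps up to 8x8 and $10^4$ random box pairs; the dataset-protocol check
generates 1400 scenes at 64 pixels; the overfit sanity check trains a
width-0.25 model on one 96-pixel scene for 500 steps (hard objectness
labels, see above) and requires total loss below 0.05; the end-to-end
check trains a width-0.25 model on 200 scenes at 128 pixels for 20
epochs at batch size 4 (small batches give more update steps on a small
dataset) and requires AP50 of at least 0.5 on 50 held-out scenes.

The end-to-end check uses short-horizon training settings rather than
the long-run protocol defaults: learning rate 3e-3 decayed with the
cosine schedule, Adam `beta1 = 0.9`, and the localization term weighted
at 0.5 instead of 0.05. The rationale: in a 1000-step run the box
regressor sees each positive anchor only a few hundred times, so the
box term needs weight comparable to the objectness term to converge in
time, and a decaying higher learning rate buys the equivalent of many
more small steps. The soft detached-CIoU objectness label is kept here
(unlike in the overfit check) because ranking detections by
localization quality is exactly what average precision measures — with
hard labels, scores carry no quality signal and greedy NMS keeps
poorly localized boxes.

Other numerical conventions: boxes are continuous, 0-based, top-left
origin, corners inclusive (area = width x height, no half-open pixel
semantics); zero-area/zero-area IoU is defined as 0; average precision
uses all-point precision-envelope integration for both AP50 and AP75
(11-point interpolation is available behind a flag, since the older
protocol is sometimes wanted); VOC XML corners are 1-based inclusive
and shifted on read/write; batch-norm epsilon is 1e-5; convolution
weights use He initialization.

## Known limitations

* Training is single-threaded, double-precision CPU: suitable for the
  desk-scale experiments here, not for 640-pixel full-scale training.
* The layer numbering of the published architecture (10, 20, 23) cannot
  be fully reconstructed from its figures; the mapping used here
  (attention on the deepest tap; involution in the last two bottom-up
  fusion blocks) is recorded in the builders' tags (`h10`, `h20`,
  `h23`).
* Whether duplicated degraded images belong in the training split only
  is unspecified in the protocol being emulated; `degrade()` is kept
  orthogonal so callers decide.
* FLOP figures are reported as MACs under a documented convention and
  are not comparable across papers; only parameter counts are treated
  as calibration targets.
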