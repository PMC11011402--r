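---
title: "Detecting green fruit on green backgrounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting green fruit on green backgrounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Unripe fruit is nearly the same colour as the foliage around it. An
orchard image of green oranges, tomatoes or persimmons offers a detector
almost no colour contrast, frequent occlusion by leaves, strong exposure
variation across weather conditions — and, typically, only a few hundred
annotated images, because field collection and annotation are expensive.
`greendet` implements a single-stage anchor-based detector adapted to
exactly this regime, together with the augmentation pipeline that makes a
few hundred images trainable, and the IoU-0.5 evaluation protocol used to
report results on such data.

## The detector

The network follows the familiar backbone / neck / head decomposition of
the v5 generation of single-stage detectors. Input images are
letterboxed (aspect-preserving resize plus symmetric gray padding) to a
square input. The backbone alternates downsampling blocks with
cross-stage-partial (C3) stages and ends in fast spatial pyramid pooling
(SPPF); the neck is a top-down FPN followed by a bottom-up PAN; the head
predicts, at strides 8, 16 and 32, a `3 x (5 + n_classes)` vector per
grid cell: box offsets, objectness and class scores for three anchors.

### The Conv-AT block

The package's central component replaces each stride-2 downsampling
convolution between backbone stages with an *attention-integration*
block. Its premise: when target and background share hue, per-channel
statistics (which channels fire) and per-pixel statistics (where, across
channels, activity concentrates) carry complementary information that a
plain convolution discards. Conv-AT preserves both by concatenation
rather than addition:

$$P(X) = \mathrm{concat}(F_{CA}(X);\ F_{CBR_1}(X))$$
$$H(X) = \mathrm{concat}(F_{CBR_2}(P);\ F_{SA}(X))$$
$$W(X) = \mathrm{concat}(F_{CBR_3}(H);\ F_{CBR_4}(X))$$
$$Y(X) = \mathrm{BN}(F_{CBR_5}(W))$$

where CBR is convolution → batch norm → ReLU (ReLU rather than SiLU:
cheaper, and convergence on small data is faster), CA is channel
attention and SA spatial attention. The closing batch normalization is
applied *on top of* CBR\_5's own: repeated concatenation widens the value
spread, and the extra normalization tames it.

Channel attention computes
$X \cdot \sigma(\mathrm{MLP}(\mathrm{Avgpool}(X)) +
\mathrm{MLP}(\mathrm{Maxpool}(X)))$: global average and max pooling over
space give two C-vectors, a shared bottleneck MLP (C → C/r → C, ReLU
between, no biases) maps each, and the summed output passes through a
sigmoid to give per-channel weights in (0,1). Spatial attention pools
*across channels* (mean and max), giving two H×W maps whose 2-channel
concatenation must be reduced to one channel before it can weight the
C-channel input; the formula's printed shapes force a 2→1 reduction, and
we implement the minimal operator satisfying them — a learned per-pixel
linear mix (a 1×1 convolution over the two pooled channels), sigmoid
after. Whether the original design hid more structure in that "MLP" is
not decidable from the reference description; ours is documented as a
choice, and the package's tests pin its exact arithmetic.

Two analytic fixed points make the attention blocks testable without
reference outputs: with all learned parameters zero, both CA and SA
multiply the input by exactly σ(0) = 0.5, and the full Conv-AT block
equals the equation-by-equation composition of its tested sub-blocks.

### Channel plan and stride matching

The defining equations give no channel widths. We use: CBR\_1 and
CBR\_4 project `c_in → c_out/2` and carry the block's stride; CBR\_2 and
CBR\_3 bring their concatenated inputs back to `c_out/2`; CBR\_5 maps to
`c_out`. The attention paths preserve the input and are stride-matched
with non-overlapping average pooling so concatenations align spatially.
Attention reduction defaults to r = 16 with a hidden-width floor of 8
(the convention of this attention family); the miniature configurations
use r = 4 because their channel counts sit below 16.

### FPN/PAN orientation

Written descriptions of this detector family sometimes invert the
FPN/PAN sampling directions; we implement the conventional orientation —
a top-down FPN carrying semantics to the fine scales, a bottom-up PAN
carrying localization back up — and note the ambiguity here rather than
reproduce it.

## Augmentation

Three augmentations are scheduled per training sample, each by an
independent Bernoulli draw, with defaults matching the study conditions:

* **Mask-guided Copy-Paste** (probability 1.0): paste 4 fruit and 15
  leaf instances per image, each cut from a source image along its
  instance mask, randomly flipped, rotated (±10°) and scaled (0.5–1.5),
  and composited with nearest-neighbour resampling so pasted pixels are
  *exactly* a transform of source pixels (an exactness the tests
  assert). Fruit pastes append exactly one box each and retry placement
  until overlap with existing fruit boxes is ≤ 0.3 IoU (20 attempts,
  then skip with a warning); leaves append no boxes. A pre-existing box
  is dropped only when pasted instances cover more than 90% of its area
  — the reference description is silent here, so the threshold is
  configurable. In the reference workflow the masks come from a promptable
  segmentation model; this package defines the provider as a contract
  (`get_instances()`), which the synthetic generator fulfils with ground
  truth.
* **Mosaic** (probability 0.8): four images, each resized to the preset
  size, spliced around a random centre on a double canvas, cropped back
  to the preset size around that centre, then flipped/rotated/HSV-jittered.
  Clipped boxes are dropped below 10% visible area or a 2-px side.
  Whether the original crops or rescales the double canvas is not
  stated; we crop, centred on the mosaic centre.
* **Mixup** (probability 0.3): pixel blend
  $\tilde x = \lambda x_i + (1-\lambda) x_j$ with
  $\lambda \sim \mathrm{Beta}(\alpha,\alpha)$, labels *concatenated
  unweighted* — detection Mixup keeps both box sets at full weight,
  unlike classification Mixup, and we follow that literally; overlapping
  boxes are deliberately not deduplicated. The Beta parameter is never
  stated in the reference description; its example blends (λ = 0.35, 0.45)
  concentrate near 0.5, so we default to α = 8 (SD ≈ 0.12), exposed as
  configuration.

## Loss and training

Ground truths are assigned by the ratio rule — a gt matches an anchor
when `max(w/wa, wa/w, h/ha, ha/h) < 4` — at its cell and the two nearest
neighbour cells. The loss is the v5-family composite: CIoU box
regression (mean of 1 − CIoU over assignments), binary cross-entropy
objectness with CIoU-valued soft targets balanced 4/1/0.4 across the
three scales, and binary cross-entropy classification. Optimization is
SGD with momentum 0.9, linear warmup and a cosine schedule.

The gradient engine is a small reverse-mode tape over channel-first
tensors, with compiled im2col convolution and pooling kernels; every
operator is validated against central finite differences in the test
suite (relative error ~1e-10). The CIoU term's gradient with respect to
the four raw box activations is taken by central differences per
assignment — four scalars per matched box, numerically exact at ε = 1e-4
and immune to sign errors in a hand-derived CIoU chain rule; the BCE
gradients are analytic. The objectness soft target is detached, as is
conventional.

**Loss weights at desk scale.** The canonical v5 weights
(box 0.05 / obj 1.0 / cls 0.5) are tuned for runs of tens of thousands
of optimizer steps. The desk-scale studies in this package train for a
few hundred steps, where the box term's mean-over-assignments
normalization leaves its per-step gradient roughly two orders of
magnitude below what localization needs. The package therefore defaults
to box 2.0 / obj 1.0 / cls 0.5, which brings the box and objectness
gradients to comparable scale in this regime; all three are exposed in
`train_hyp()` and full-scale users should restore the canonical values.

## The synthetic orchard generator

The full-scale field datasets this problem is studied on (hundreds of
2560×1920 orchard photos per crop) are not publicly deposited, so the
package generates its own study conditions: scenes whose fruits share
hue with the foliage behind them.
The generator emulates, in order of importance:

* the **similar-colour premise** — fruits sit `hue_delta` (default 12°)
  from the foliage hue (110°), with matched saturation/value ranges;
* **occlusion** — lens-shaped leaf lobes composited after (over) the
  fruit, preferentially centred on fruit boundaries;
* **exposure variation** — a per-scene brightness factor (0.75–1.25)
  standing in for sunny/cloudy/overcast acquisition, plus pixel noise;
* **size variation** — fruit radii spanning the three detection strides.

Boxes are amodal (they cover occluded fruit extent, the common field
annotation practice) and every instance carries its full binary mask, so
mask-guided Copy-Paste needs no segmentation model. What the generator
does **not** emulate: true foliage texture and clutter, specular leaf
highlights, camera optics, perspective, or within-class shape variety
beyond shaded ellipses. Tests passing on these scenes therefore validate
the *machinery* — label bookkeeping, attention arithmetic, loss
geometry, metric computation — not field-level accuracy; the published
field numbers (mAP 84.6% oranges / 98.0% tomatoes / 85.1% persimmons)
are neither reproducible nor claimed here.

Defaults: 640×640 scenes, 1–8 fruits of radius 12–60 px, 5–20 leaves,
occlusion probability 0.5 (`scene_config()`); the desk-scale variant
(`scene_config_desk()`) uses 160×160 scenes, 1–3 fruits of 12–32 px and
3–8 leaves so a full train/evaluate cycle fits in CPU minutes.

## Evaluation protocol

A detection is a true positive when its IoU with a still-unmatched
ground truth of the same category is strictly greater than 0.5 (ties at
exactly 0.5 count as false positives); detections are matched greedily
in confidence order, each ground truth at most once. Precision, recall
and F1 = 2PR/(P+R) are reported at the confidence maximizing F1 (the
family convention; the reference description does not state an operating point). AP
integrates the monotone envelope of the precision-recall curve with
all-point interpolation — the interpolation convention is not stated there
either, so the suite pins ours against a brute-force threshold-sweep
oracle to 1e-9. mAP is the unweighted mean of per-category APs;
categories without ground truth are excluded with a warning.

## Numerical and degenerate-input choices

* Pixel coordinates are 0-based with half-open boxes; normalized labels
  are center-format (the YOLO dialect), written at 6 decimals.
* The 7:3 train/test split takes `floor(0.7 N)` training ids. (The
  published per-dataset counts are internally inconsistent with any
  single rounding rule — 326/142 of 468 and 198/83 of 281 are each one
  or two off exact 7:3 — so a single rule was standardized.)
* Empty label files are valid (background images); empty scenes are
  valid; a category with no ground truth has undefined AP and is
  excluded from mAP with a warning rather than scored 0.
* `1 - IoU` anchor clustering accepts a centroid update only while the
  clustering objective improves, then mutates anchors, keeping each
  mutation only if best-possible recall rises; with fewer boxes than
  anchors it falls back to the canonical 640-scale nine with a warning.
* All randomness flows through explicit seeds; a master seed fans out
  to per-stage seeds so any stage can be re-run in isolation.

## Desk-scale study sizes

The self-contained study run by `run_desk_study()` (and by
`scripts/acceptance.R`) trains the miniature detector — widths
8/16/32/64/96, single bottlenecks, attention reduction 4 — on 64
synthetic 160×160 scenes, evaluates on 16 held-out scenes, and reports
mAP@0.5 from the best-validation epoch. These sizes were chosen so the
whole study completes in roughly ten minutes on one CPU core while still
giving the detector enough data to clear chance comfortably; they are
the package's reference conditions, not a claim about field data.

## Known limitations

* The backbone positions receiving Conv-AT blocks are configurable but
  default to *all four* inter-stage downsamplings; the reference diagram is
  not legible enough to pin the original placement.
* Evaluation-mode batch-norm statistics lag the weights in very short
  runs (momentum 0.1); the desk studies are long enough for this to be
  a small effect (~0.04 mAP in our measurements), but very short custom
  runs should expect it.
* The pure-R tape is fast enough for desk-scale work only; full-scale
  training of the reference architecture requires a GPU framework and is
  out of scope.
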