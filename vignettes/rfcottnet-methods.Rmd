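---
title: "Methods: a multi-exit hybrid attention classifier with INT8 quantization-aware training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-exit hybrid attention classifier with INT8 quantization-aware training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, the
training and inference procedures, the quantization scheme, the synthetic
corpus the test suite runs on, and the numerical and design choices that were
genuinely open. Everything written here is computed by the package's own
functions, tests, or the acceptance script; no empirical claim below goes
beyond what those runs produce.

## The problem

Cotton disease and pest diagnosis from leaf photographs is an 11-way image
classification task (ten disease/pest categories plus healthy leaves) that
must run on resource-constrained field hardware. The design goal is therefore
threefold: a compact hybrid convolution/attention backbone, *dynamic
early-exit inference* so easy images pay less compute, and an *INT8
quantization-aware-training (QAT)* path so the deployed model fits in a few
megabytes without losing accuracy.

## The backbone

The feature extractor is a MobileViTv2-style hybrid. A strided 3x3 stem is
followed by MobileNetV2 inverted-residual blocks (pointwise expand ->
depthwise 3x3 -> pointwise project, residual when stride 1 and the channel
counts match, expansion factor 2, batch norm + SiLU) and three MobileViT
stages. Each MobileViT stage is a down-sampling MV2 block plus a MobileViT
block: a local representation (depthwise 3x3, pointwise to token width *d*),
an unfold of the feature map into 2x2-patch token groups, a stack of pre-norm
transformer layers, a fold back, a pointwise projection to the input width,
and an identity-residual fuse with the block input. The default stage table
is

| stage | blocks | width | attention width d | depth |
|---|---|---|---|---|
| stem | conv 3x3, stride 2 | 32 | - | - |
| 1 | MV2 | 64 | - | - |
| 2 | MV2 (down) + MV2 x2 | 128 | - | - |
| 3 | MV2 (down) + MobileViT | 256 | 128 | 2 |
| 4 | MV2 (down) + MobileViT | 384 | 192 | 4 |
| 5 | MV2 (down) + MobileViT | 512 | 256 | 3 |

followed by global average pooling and a linear classifier. All widths scale
with `width_multiplier`; the whole table is exposed in `stage_config()` so
the parameter budget can be matched exactly. At full width with three exit
heads (head width 336) and 11 classes the model has 4,852,044 trainable
parameters -- 4.9 M to one decimal -- as `count_params()` reports and
`scripts/acceptance.R` recomputes.

### Separable self-attention

Inside each transformer layer, attention is the *separable* variant: instead
of a k x k token-affinity matrix, a learned score projection `W_I` (d -> 1)
produces context scores `cs = softmax(x W_I)` over the k tokens; a single
global context vector

    cv = sum_i cs_i * (x W_K)_i

is formed, and each token's output is

    y_i = (cv * ReLU((x W_V)_i)) W_O,

with `*` the broadcast element-wise product. Cost is linear in k (the
profiler counts `k d + 2 k d^2 + k d + k d + k d^2` MACs per token group, and
the test suite asserts exact linearity in k). Two readings were genuinely
open and are worth recording:

* the normalizer producing `cs` is not uniquely pinned down by the
  description "contextual weight"; softmax over `x W_I` is used, following
  the reference separable-attention design, and the brute-force oracle in the
  tests uses the same reading;
* the ReLU in the value branch is taken literally even though the
  convolutional blocks use SiLU.

The attention operator is position-equivariant (no positional terms), the
context scores always form a probability simplex, and the vectorised
implementation is tested against a scalar-loop brute-force evaluation on 100
seeded random instances at 1e-6.

## Multi-exit training and dynamic inference

Three auxiliary heads (pointwise conv to the head width, global average
pool, linear classifier) attach after the three MobileViT stages; with the
final classifier the model emits four ordered stage predictions. Training
minimises the joint loss: each stage's batch-mean cross-entropy, combined as
an *unweighted sum over all four stages* (`lambda_i = 1`, configurable). The
combination rule is a design decision -- the per-stage losses are defined
individually and no combination weights are published -- and whether the
final classifier participates in the sum was also unstated; including it with
unit weight trains the trunk and all exits jointly and makes every parameter
reachable by gradient (asserted per tensor in the tests).

At inference, stages are evaluated in order and gated. Two gate readings are
shipped because the printed description and the algorithm box disagree:

* **confidence mode** (default): exit at the first stage whose softmax
  maximum *strictly exceeds* its threshold; defaults (0.6, 0.7, 0.8) are the
  published constants;
* **entropy mode**: exit at the first stage whose prediction entropy (nats)
  is *strictly below* S; a scalar S applies to every early stage unless a
  per-stage vector is given.

Ties do not exit (strict inequalities, taken literally). The final stage
always returns. Disabled exits (thresholds above 1, or S = 0) reproduce the
plain final-head forward pass exactly, lowering confidence thresholds can
only move exits earlier, and computation after an exit is genuinely not
performed -- all three are asserted in the suite, the last via an evaluation
counter. `exit_statistics()` plus the profiler's cumulative per-stage MAC
table quantify the expected cost `sum_i fraction_i * cumulative_i`; the
cumulative cost of stage i includes the auxiliary heads evaluated along the
way, which keeps the vector non-decreasing.

## Quantization-aware training and INT8 export

The QAT path follows the standard five steps: FP32 baseline; insertion of
fake-quantization nodes; fine-tuning with the nodes active; retention of the
per-layer quantization parameters; INT8 export. The published description
names QAT but no scheme, so the de-facto INT8 recipe is adopted and recorded
in `quant_spec()`:

* weights: symmetric per-output-channel, codes in [-127, 127];
* 1-D parameter vectors (biases, norm affines): symmetric per-tensor;
* activations: asymmetric per-tensor, codes in [-128, 127], EMA min/max
  observers with momentum 0.99;
* round half to even; straight-through estimator on the backward path;
* first and last layers are quantized like every other layer -- the printed
  storage budget implies near-total 1-byte coverage.

Every quantization scale is rounded to float32 precision at the moment it is
computed, and `freeze_ranges()` also float32-rounds the batch-norm running
statistics. This makes the in-memory fake-quant model and the serialized
container numerically identical, so the exported model's exit decisions
match the fake-quant model's decisions input for input (asserted on 100
synthetic images).

The export container is a single self-describing file: a JSON header
(architecture, per-tensor layout, per-layer activation scale/zero-point)
followed by a binary payload of INT8 codes and float32 scales/running
statistics. Loading it rebuilds the model and reproduces the quantized
forward pass; export -> load -> re-export is byte-identical. At full width
the file measures just under 4.8 MB (1024^2 bytes): 4,852,044 one-byte
weights plus about 176 KB of scales, running statistics and header.

## The synthetic corpus

No real cotton imagery ships with the package; the generator emulates the
corpus the pipeline is designed for so every stage is testable offline. Each
image is an elliptical leaf on a textured soil-toned background; class
identity is encoded in the *visual signature*: lesion count range, lesion
colour (hue/saturation/value), lesion size, leaf hue shift, and texture
noise. The 11 default signatures are loose caricatures of the field classes
(many small yellow dots for aphids, large dark ragged spots for army worm,
leaf-wide yellowing for fusarium wilt, white powder specks for powdery
mildew, and so on), chosen once so that classes are learnable by
construction -- a nearest-centroid classifier on mean colour already
separates them well above chance, which the suite asserts. Default per-class
totals reproduce the emulated corpus' class imbalance (6,444 healthy down to
116 leaf variegation; 18,953 in all) and scale by a single factor.

What the generator does *not* emulate: real lesion morphology and texture,
illumination and background variation of field photographs, label noise, and
cross-source domain shift. A green test suite on this corpus therefore
demonstrates that the pipeline's machinery (rendering, augmentation,
splitting, training, exits, quantization, metrics) is correct and that the
architecture can fit a colour/shape-separable 11-class problem -- not that
the model reaches any particular accuracy on real cotton imagery.

The dataset-construction pipeline mirrors the published accounting:
augmentation produces exactly `variants_per_original` images per field
original *including* the unmodified original (so 796 originals x 6 = 4,776),
each variant applying an independently sampled subset of five operators
(brightness +-30%, horizontal/vertical flips, 1-20 random rectangle masks of
2-20% of the image side, Gaussian noise sigma 10 on the 0-255 scale, rotation
uniform in +-30 degrees; ranges are defaults, all configurable, none
published). The stratified splitter assigns `floor(train_fraction * n)` of
each class to training -- the rule that reproduces every row of the published
class table at 8:2 -- with membership chosen by a seeded within-class
shuffle. Whether augmented variants of one original may straddle the
train/test boundary is unstated; the default keeps a family in one split,
which is stricter than anything published, at the price of the per-class
train count occasionally falling short of the floor target by at most one
family.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds through a splittable
  derivation (a rolling string hash), so no global RNG state leaks between
  stages; identical seeds give byte-identical corpora and identical trained
  weights.
* Batch norm uses momentum 0.9 and eps 1e-5; layer norm eps 1e-5. In
  evaluation mode batch norm uses running statistics, so per-sample dynamic
  inference matches batched evaluation.
* Cross-entropy clamps probabilities at 1e-12; entropy uses the 0 log 0 = 0
  convention; metrics use the 0/0 -> 0 convention for precision, recall and
  F1.
* Zero-range observers freeze to a small positive scale (1e-8) rather than
  dividing by zero; an all-zero weight tensor gets scale 1.
* Images are stored on the 8-bit grid ([0, 1] in steps of 1/255); rotation
  uses nearest-neighbour resampling with zero fill, so a logged angle
  re-renders bit-identically.
* Class labels are 1-based in the R API; manifests store class names.
* Inputs must be divisible by 32 and then by the patch size; violations are
  reported as shape errors rather than silently padded.

## Desk-scale problem sizes

CPU-only runs (the test suite, CI) use the desk-scale preset: the same
architecture at one-eighth width (`rfc_config_tiny()`: widths 4-64,
attention widths 16/24/32, depth 1 per stage, head width 44, 64 x 64
inputs), a synthetic corpus of 60 images per class split 8:2, 18 epochs of
AdamW (batch 32, learning rate 4e-3 decaying by 0.88 per epoch after epoch
10, random flips as regularisation), then 2 epochs of QAT fine-tuning at
5e-4. These sizes are the package's choice of a scaled-down study: large
enough that the end-to-end test reaches >= 90% FP32 test accuracy with INT8
within 2 points, small enough to run in minutes. The paper-scale training
defaults (batch 128, learning rate 5e-5, full width, 256 x 256) are wired to
`preset: full` in the run configuration and the `rfcott` command-line tool,
but full-scale training is not exercised by the tests.

## Known limitations

* The synthetic corpus is a proxy; no claim about real-image accuracy is
  made or tested.
* FLOPs are analytic multiply-accumulate counts (normalizations and
  activations excluded; one MAC = one FLOP). Published FLOP figures for
  quantized models depend on accounting conventions that cannot be recovered
  from prose, so the profiler reports full-path and expected-dynamic-cost
  numbers separately and asserts no equality with any printed FLOP value.
* Wall-clock latency is hardware-dependent and out of scope.
* The INT8 container is executed as dequantized arithmetic in R; it encodes
  exactly what an integer runtime would need (codes, scales, zero points)
  but no integer-kernel speedup is claimed.
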