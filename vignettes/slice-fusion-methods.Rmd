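---
title: "Attention-based multi-view slice fusion: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multi-view slice fusion: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amsf)
```

## The problem and the model

`amsf` classifies skull-stripped structural brain MRI volumes into three
stages — Alzheimer's disease (AD), mild cognitive impairment (MCI) and
normal control (NC) — by combining two complementary feature routes:

1. **Multi-view 2D slice features.** The preprocessed cube is cut along
   the three anatomical axes (sagittal, coronal, axial). For each view
   the *n* central slices form a slice cluster
   $C_v = [C_v^1, \dots, C_v^n]$; a per-view slice feature extraction
   network (SFEN: four blocks of 3×3 convolution, batch norm + ReLU, 2×2
   max pooling, then global average pooling) maps each slice to a
   *d*-vector, giving the stack
   $T_v = [T_v^1, \dots, T_v^n] \in \mathbb{R}^{n \times d}$
   (40 × 1 × 128 at full scale).
2. **A global 3D feature.** A four-block 3D CNN of the same block
   structure (GFE) summarizes the entire volume into a *g*-vector.

The contribution of interest is the **slices fusion attention (SFA)**
module, which replaces naive slice pooling. It has two stages:

* a 1×1 score head compresses each slice's *d* channels to a scalar,
  and a softmax **across the n slices** turns these into attention
  scores $a \in \Delta^{n-1}$; the context features are the re-scaled
  rows $S_v^i = a_i T_v^i$;
* a channel bottleneck $d \to d/r \to d$ (1×1 convolutions with batch
  norm + ReLU in the middle) maps $S_v$ to per-slice, per-channel
  re-weighting coefficients $A_v \in \mathbb{R}^{n\times d}$, and the
  fused view feature is $F_v = \sum_{i=1}^{n} T_v^i \odot A_v^i$.

The three view features and the global feature are concatenated
(order: sagittal, coronal, axial, global) and a single fully-connected
layer produces the three class logits; softmax gives probabilities.
Five ablation variants share this skeleton: `3d` (GFE only), `2d`
(slice branches with non-attention fusion), `2d3d`, `se2d3d`
(squeeze-and-excitation slice gating) and `amsf` (SFA).

Two readings of the source equations are ambiguous and were resolved as
follows. The per-slice weight symbol in the SFEN equation would imply 40
independent networks per view; the accompanying text says one network
*per view*, which is the default here (weight sharing across slices,
slices processed as a batch), with `per_slice_weights = TRUE` available
for the literal reading. Second, the dimensional role of the context
product admits either a pooled *d*-vector or an *n×d* re-scaled stack;
the *n×d* reading is implemented because only it is consistent with the
bottleneck "raising the number of channels to the original number"
while still allowing the final per-slice sum.

## Preprocessing

`preprocessVolume()` = crop → resize → standardize:

* **Background cropping** keeps the minimal bounding box of non-zero
  voxels. Background is *exactly zero* intensity (the convention of
  skull-stripped data and of the phantom simulator); no threshold is
  applied.
* **Trilinear resize** to an isotropic cube (default side 90, pixel-center
  alignment). Trilinear is the standard choice for intensity MRI;
  nearest-neighbour would alias the small structures of interest and
  higher-order splines can overshoot near the background boundary.
* **Non-zero-region standardization**: non-zero voxels are mapped to
  zero mean and unit standard deviation; zero voxels stay exactly zero
  so the background remains inert downstream.

The "middle n slices" window along an axis of length S starts at
`floor((S − n)/2)` (0-based); an odd leftover puts the extra margin on
the high-index side. Voxel indices are 0-based in all user-facing
slice-index fields. The crop offsets and per-axis resize scales are
recorded in the volume's metadata so spatial annotations (e.g. the
phantoms' ground-truth band) can be mapped into preprocessed
coordinates.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `side` | 90 voxels | preprocessed cube side |
| `n_slices` | 40 | central slices per view |
| `feature_dim` (d) | 128 | SFEN output channels (widths 16–32–64–128) |
| `global_dim` (g) | 64 | GFE output channels (widths 8–16–32–64) |
| `reduction` (r) | 8 | SFA bottleneck ratio (d divisible by r) |
| `se_reduction` | 8 | SE bottleneck ratio (n divisible by it) |
| `batch_size` | 12 | SGD minibatch |
| `epochs` | 100 | training passes |
| `learning_rate` | 0.01 | SGD step size (fixed) |
| `momentum` | 0.9 | SGD momentum |
| `train_fraction` | 0.7 | stratified holdout split |

The optimizer (SGD with momentum 0.9), the cross-entropy loss, the
channel widths, g = 64 and r = 8 are this package's choices where the
source recipe names only batch size, epochs and learning rate. The
70/30 split is stratified by class; a k-fold option (`splitFolds()`)
exists, but a single holdout split is the default, and the held-out
30% doubles as the validation set for the learning curves.

Two optional stabilizers extend the fixed-learning-rate recipe and are
off by default except where noted: per-minibatch gradient clipping to a
global L2 norm (default 5; a fixed 0.01 learning rate with momentum
otherwise produces occasional destructive steps on small datasets) and
a one-step learning-rate decay (`lr_decay_epoch`, factor 0.1). The SFA
score head is randomly initialized so that the softmax is non-uniform
from the first step and the scores receive useful gradients; an
alternative uniform-fusion starting point (zero score head, bottleneck
output bias 1/n, i.e. an untrained module that reproduces mean fusion
exactly) is available via `initSfa(n_slices = )` — it trains very
stably but, on tasks the other branches can already solve, tends to
leave the attention distribution near uniform, which defeats the
purpose of the module.

## Numerical choices

* Batch-norm: eps 1e-5, running-statistic momentum 0.1; evaluation mode
  uses running statistics, so single-example inference is deterministic.
  In the SFA bottleneck the batch dimension is the set of all slice
  positions in the minibatch.
* Max pooling uses floor semantics (odd trailing rows are dropped) and
  routes ties to the first window cell in scan order.
* Convolution padding 1, stride 1; conv layers carry no bias (the
  batch-norm shift absorbs it).
* Softmax is computed with max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* He-normal weight initialization; the classifier uses sd
  `sqrt(1/fc_in)`.
* Degenerate inputs fail loudly: all-zero volumes cannot be cropped,
  constant non-zero regions cannot be standardized, slices below 16×16
  cannot pass four poolings, and a non-finite training loss aborts with
  the epoch and batch.
* One global seed fans out to independent sub-seeds (dataset noise,
  split, initialization, shuffling) via a deterministic hash of the seed
  and a role string (`deriveSeed()`), so runs are bit-reproducible on
  one machine.

The compute engine stores activations channel-first as
`(C, spatial × batch)` matrices; convolutions are an im2col gather plus
one BLAS matrix product (with a direct compiled path for the
single-channel first layers), and pooling/batch-norm inner loops are
small compiled kernels. Analytic gradients for every variant are
verified against central finite differences in the test suite.

## The phantom simulator

`generatePhantom()` emulates exactly the features of skull-stripped MRI
that the pipeline consumes: a zero background; a bright foreground
ellipsoid ("brain", intensity 1.0, radius 0.45 of the side with 3%
per-axis jitter and ±1 voxel center jitter); a darker inner ellipsoid
("ventricle-like", intensity 0.3) whose radius is `0.09 × side` scaled
by the class effect (NC 1.00, MCI 1.15, AD 1.30, strictly ordered);
additive Gaussian noise (sd 0.1 of the foreground intensity) on
foreground voxels only. The inner structure is confined to a centered
informative band (default: the central 30% of every axis), so class
evidence is slice-localized and attention recovery is measurable. The
simulator validates that the largest class's structure fits inside the
band and the foreground, and errors otherwise.

The foreground radius 0.45 is chosen so that background cropping
rescales the volume only mildly (≈ 7%), keeping the informative band's
width in preprocessed coordinates close to its generated width; with a
much smaller foreground, cropping stretches the band toward the width
of the slice window and the band-concentration ratio becomes bounded
near 1 by construction, independent of what the model learns. For the
same measurability reason the desk-scale experiments use a slice
window about twice the mapped band width.

What the phantoms do **not** model: anatomy, registration error, bias
fields, Rician noise, partial-volume tissue mixtures, scanner effects.
A model that passes every phantom-based test has demonstrated that the
architecture, gradients, training loop and attention mechanism work —
not that it diagnoses dementia; clinical data remain necessary for any
claim about real MRI.

One subtlety is worth knowing: per-volume intensity standardization
couples the inner-structure size (the class) to the global mean, so
after preprocessing *every* foreground voxel carries a weak class
signal. In generated (unnormalized) space the out-of-band voxels are
class-identical (verified by a two-sample test), but the attention
module operates post-normalization, where out-of-band slices are only
*less* informative, not uninformative.

## Desk-scale study sizes

The full-scale configuration (90³, 40 slices, d = 128) is exercised for
shape contracts; learning experiments run at a desk scale chosen once:
side 32, 28 slices per view, d = 32 (widths 8–16–32–32), g = 16, r = 8,
75 phantoms per class (50 train / 25 test per class after the
stratified 2/3 split), batch 12, learning rate 0.01 with a 0.1 decay
step after epoch 18, clipping at 5, at most 30 epochs. The
ablation-ordering experiment (attention vs mean fusion under a band
confined to 25% of slices) runs 5 seeds at a further reduced size —
27 phantoms per class (18 train / 9 test), d = 16, g = 8, 20 epochs
with decay after 14 — enough training signal for both variants to leave
chance while keeping ten full trainings tractable; per-seed accuracies
are printed by the test for inspection.

## Known limitations

* CPU-only, double precision; full-scale (90³) *training* is
  correspondingly slow — the full-scale path is validated for forward
  shape contracts and the learning claims are made at desk scale.
* The `2d` variant's slice fusion is a design decision (mean by
  default, `fusion = "concat"` for the splicing reading); the source
  does not specify it.
* Single-channel input only (one structural modality).
* The SE baseline follows the standard squeeze-and-excitation recipe
  over slices-as-channels; the source cites SE by name only.
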