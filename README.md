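# amsf — attention-based multi-view slice fusion for structural brain MRI

`amsf` is an R package for three-class staging of structural brain MRI
— Alzheimer's disease (AD), mild cognitive impairment (MCI), normal
control (NC). Most volumetric classifiers either analyse a handful of
2D slices from one orientation or push the whole 3D volume through one
network; this package implements the combined route: per-view 2D slice
features, fused by a learned attention over slices, concatenated with a
global 3D feature.

Given a preprocessed cube, the *n* central slices of each anatomical
view (sagittal, coronal, axial) are encoded by a per-view CNN into a
feature stack `T_v ∈ R^{n×d}`. The slices fusion attention (SFA)
module computes softmax attention scores across slices from a 1×1 score
head, re-scales the rows into context features `S_v^i = a_i T_v^i`,
passes them through a channel bottleneck `d → d/r → d` (batch norm +
ReLU inside) to get per-slice per-channel weights `A_v`, and fuses

    F_v = Σ_{i=1..n} T_v^i ⊙ A_v^i .

The three view features plus the global 3D feature feed one
fully-connected layer and a softmax over (AD, MCI, NC). Five ablation
variants are provided: `3d`, `2d`, `2d3d`, `se2d3d`
(squeeze-and-excitation slice gating) and `amsf` (SFA).

Everything around the model is included: NIfTI input, the
preprocessing chain (background crop → trilinear resize to a cube →
non-zero-region standardization → central multi-view slicing), a CPU
training loop (SGD + momentum, cross-entropy, per-epoch history,
best-checkpoint retention), macro one-vs-rest metrics with ROC/AUC, an
ablation harness, and a synthetic brain-phantom simulator with
slice-localized class structure so the whole pipeline is testable
without clinical data. The neural-network layers (2D/3D convolution,
batch norm, pooling, attention) are implemented in the package itself
on BLAS matrix products with small compiled kernels; gradients are
verified against finite differences in the test suite.

## Worked example

Generate a small phantom dataset, train the attention variant, and
inspect where it looks:

```r
library(amsf)

ds  <- generateDataset(phantomSpec(side = 32, n_per_class = 40), "phantoms", 7)
man <- loadManifest("phantoms/manifest.csv")
sp  <- splitDataset(man, 0.7, seed = 7)

cfg <- modelConfig("amsf", side = 32, n_slices = 28, feature_dim = 32,
                   sfen_widths = c(8, 16, 32, 32), global_dim = 16,
                   gfe_widths = c(4, 8, 16, 16), reduction = 8,
                   se_reduction = 4, seed = 7)
tc  <- trainConfig(batch_size = 12, epochs = 20, learning_rate = 0.01,
                   clip_norm = 5, lr_decay_epoch = 14, seed = 7)
fit <- trainModel(buildModel(cfg), sp$train, tc, val_manifest = sp$test,
                  base = "phantoms")
met <- evaluateModel(fit$best, sp$test, base = "phantoms")
met
```

```
AmsfMetrics
  acc 0.8889  sen 0.8889  spe 0.9444  pre 0.8897  f1 0.8861  auc 0.9907
     predicted
truth AD MCI NC
  AD  12   0  0
  MCI  1   9  2
  NC   0   1 11
```

Accuracy is the trace of the confusion matrix over the test size;
`sen`/`spe`/`pre`/`f1` are macro one-vs-rest averages over the three
classes; `auc` is the macro one-vs-rest area under the ROC curve. A
single volume is classified with

```r
v <- preprocessVolume(loadVolume("phantoms/AD_001.nii.gz"), 32)
predictVolume(fit$best, v)$probabilities
```

```
          AD          MCI           NC
1.000000e+00 9.528117e-22 4.073466e-55
```

and `attentionTable(fit$best, list(v))` tabulates the per-slice
attention scores of each view; on this run its top rows are the central
sagittal slices 15-18 — inside the band of slices that carries the
phantoms' class structure:

```
       volume_id     view slice_index      score
17 AD_001.nii.gz sagittal          18 0.09255090
15 AD_001.nii.gz sagittal          16 0.09037090
14 AD_001.nii.gz sagittal          15 0.08671844
16 AD_001.nii.gz sagittal          17 0.06924143
54 AD_001.nii.gz  coronal          27 0.06246712
```

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/amsf.R simulate --side 32 --n_per_class 40 --seed 7 --out phantoms
Rscript inst/cli/amsf.R train    --manifest phantoms/manifest.csv --side 32 \
    --n_slices 28 --feature_dim 32 --global_dim 16 --se_reduction 4 \
    --epochs 20 --seed 7 --out run1
Rscript inst/cli/amsf.R ablate   --manifest phantoms/manifest.csv --side 32 \
    --n_slices 28 --feature_dim 32 --global_dim 16 --se_reduction 4 \
    --epochs 20 --seed 7 --out ablation1
```

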