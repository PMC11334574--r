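---
title: "Count-supervised counting networks: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-supervised counting networks: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Counting dense small objects in field imagery — wheat ears in canopy
photographs, grains scattered on a table — is usually solved with
*location-supervised* models: detectors trained on bounding boxes, or
density-map regressors trained on dot annotations.  Both annotation
styles are expensive and noisy for overlapping, elongated objects.
`countnet` implements the *count-supervised* alternative: the only
label is the per-image total, and the network regresses that scalar
directly.

The architecture has four stages:

1. **Backbone.** The first ten 3x3 convolutions of the VGG16 layout
   (widths 64,64 | 128,128 | 256,256,256 | 512,512,512, ReLU after
   each) with 2x2 max pooling after the first three blocks.  A
   square input of side $S$ becomes a 512-channel map $M_b$ of side
   $S/8$; at the native $S = 512$ that is $64 \times 64 \times 512$.
2. **Channel + spatial attention (CBAM).**  A channel gate
   $M_c = \sigma(\mathrm{FC}(\max_{hw} M_b) + \mathrm{FC}(\mathrm{avg}_{hw} M_b))$
   with one shared two-layer bottleneck (reduction ratio $r$, ReLU
   between the layers), applied as $M_{cb} = M_c \odot M_b$; then a
   spatial gate
   $M_s = \sigma(\mathrm{conv}_{k\times k}[\max_c M_{cb};\, \mathrm{avg}_c M_{cb}])$
   applied as $M_f = M_s \odot M_{cb}$.  Both gates are sigmoids, so
   every element of $M_f$ is attenuated relative to $M_b$ — a
   property the tests assert.  A pass-through mode ($M_f = M_b$)
   supports ablation.
3. **Multiscale perception (MPM).**  $M_f$ is sliced into
   non-overlapping $p \times p$ patches at several scales (defaults
   16, 8, 4, giving 16/64/256 patches on a 64-side map), each patch
   linearly projected to a shared embedding dimension $d$, and each
   scale processed by $N$ MLP-mixer layers.  A mixer layer applies a
   token-mixing MLP across the patch axis (via transposition) and a
   channel-mixing MLP across the embedding axis, each preceded by
   layer normalization and wrapped in a residual connection.  The
   three token matrices are concatenated coarse-to-fine (336 tokens
   at full scale) and mixed again by $N$ more layers.
4. **Counting head.**  The merged token matrix is flattened;
   $x_1 = \mathrm{ReLU}(\mathrm{FC}_1(\cdot))$,
   $x_2 = \mathrm{FC}_2(\mathrm{Dropout}(x_1))$, and the prediction
   is $\hat C = \mathrm{ReLU}(\mathrm{mean}(x_2))$: a set of $K$
   count guesses whose average damps single-readout variance, with a
   terminal ReLU guaranteeing $\hat C \ge 0$.

Training minimizes the L1 loss between $\hat C$ and the integer
label with SGD + momentum, batch 16, a multi-step learning-rate
schedule, and best-validation-MAE checkpointing.  Evaluation uses
MAE, RMSE and $R^2$, optionally stratified by scene density
(true count at most 40 vs. greater).

## What is implemented, and how

No deep-learning framework is used: all forward passes and all
gradients are implemented in the package (convolution as im2col plus
BLAS matrix products, with small compiled kernels for im2col/col2im
and max pooling; hand-derived backward passes for every stage).  The
entire chain is verified two ways: against independent explicit-loop
oracles for each equation, and against central finite differences
through the assembled network.  This is why the test suite can make
exact claims about the arithmetic rather than smoke-testing shapes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `input_size` | 512 px | preprocessed square input side |
| backbone `width` | 1 | channel multiplier; 1/16 for desk-scale models |
| `reduction` / `sp_kernel` | 16 / 7 | attention bottleneck ratio and spatial kernel |
| `mpm$slices` | 16, 8, 4 | patch sides; each must divide the feature side |
| `mpm$embed_dim` | 512 | shared token embedding $d$ |
| `mpm$depth` | 4 | mixer layers $N$ per branch and for the merge stage |
| `mpm$token_hidden`, `mpm$channel_hidden` | 256 / 1024 | mixer MLP widths |
| `head$hidden`, `head$k`, `head$dropout` | 1024 / 64 / 0.5 | head FC width, count-set size, dropout |
| `lr`, `batch_size` | 1e-4, 16 | optimizer defaults at full scale |

Published sources fix the slice sizes, $N = 4$, the 512 input, the
optimizer family, batch size, initial learning rate and the L1 loss.
The embedding dimension, mixer hidden widths, head width, $K$, the
dropout rate, momentum (0.9), weight decay (0) and epoch count are
not published; the defaults above are declared choices, all
configurable.  The attention defaults $r = 16$, $k = 7$ and the
shared ReLU bottleneck follow the original attention-block design.
The mixer MLPs use GELU and pre-norm residual placement, following
the original mixer design.  Concatenation order is fixed
coarse-to-fine for determinism.

## The synthetic generator

Real wheat imagery cannot ship with the package, so a seeded
generator emulates the statistical structure the model faces:

* **Counts** follow a rounded Gaussian clipped to `[min, max]`
  (boundary values absorb the tails).  Ear-field defaults mean 42,
  sd 20, range 0–190, mirroring the published per-image statistics;
  grain-scatter defaults mean 40, sd 10, range 11–68, with
  zero-count background-only negatives available by rendering
  `count = 0`.  The per-image count histogram of the real data is
  not published beyond min/max/mean, so the sd values are free
  parameters of the emulation, chosen once.
* **Objects** are oriented ellipses: elongated with a sinusoidal
  along-axis texture for ears, small rounded kernels for grains,
  with color jitter.  Partial occlusion is allowed up to a
  configurable overlap fraction (default 0.3); the label still
  counts every instance.  A placement that cannot satisfy the
  occlusion budget raises a capacity error rather than silently
  dropping objects.
* **Backgrounds** are a clutter-shaded green-brown canopy for ears
  and plain or gray-striped surfaces for grains.
* **Labels are exact by construction** and instance positions are
  kept in a debug sidecar that the model never reads, preserving the
  count-only supervision premise.

What the generator does *not* emulate: photorealistic texture,
growth stages, perspective and UAV viewpoint effects, illumination
fields, and the long-range correlations of real canopies.  Passing
the learning tests therefore demonstrates that the architecture and
optimizer can extract count signal from images under count-only
supervision — not that the published field accuracies are
reproduced.  Those require the original datasets and GPU-scale
training, which are outside this package's validation surface.

## Desk-scale validation protocol

The package validates learning capability at sizes a single CPU
handles in minutes (the sizes below are the package's own protocol):

* **Memorization:** a width-1/16 model on 128 px images overfits 8
  images in 300 steps to under 10% of its initial L1 (dropout off —
  the check is optimization sanity, so regularization noise is
  removed).
* **Generalization:** the same architecture trained on 200 synthetic
  ear-field images (mean count 20, sd 8), checkpointed by MAE on a
  held-out 50-image validation set, must beat the
  predict-the-training-mean baseline's test MAE by at least 30%
  (median over three seeds) on a further 50-image test set.  Fourteen
  epochs at lr 2e-3 with decay steps at epochs 9 and 12 are used; the
  published lr of 1e-4 is tuned to an ImageNet-pretrained full-width
  backbone and is far too small for a from-scratch width-1/16 model.
* Training initializes the output bias to the mean training count,
  so the untrained model starts at the prior mean.  This is standard
  for count regression: it removes the offset warmup and keeps the
  terminal ReLU away from its dead zone (where $\mathrm{mean}(x_2) < 0$
  makes all gradients vanish).

## Numerical choices and degenerate inputs

* Layer normalization uses $\epsilon = 10^{-6}$; He-scaled Gaussian
  initialization everywhere; biases start at zero.
* Channel-max and spatial-max pooling break ties by first index;
  gradients route to the argmax element only.
* Dropout is inverted (scaling by $1/(1-p)$ at train time) and is
  disabled at evaluation, so evaluation is bit-for-bit
  deterministic.
* $R^2$ follows its defining formula literally and may be negative;
  a constant truth vector makes it undefined and raises an explicit
  error rather than returning NaN.
* Attention heatmaps (regression Grad-CAM) weight each channel by
  the spatial mean of $\partial \hat C / \partial A$, apply ReLU,
  upsample bilinearly and min-max normalize; an all-zero map is
  returned as all zeros rather than dividing by zero.  Mixer-branch
  token matrices are reshaped to their patch grid so every scale is
  visualizable.
* Bilinear resampling uses half-pixel centers with edge clamping;
  counts are resize-invariant so labels need no adjustment.
* Non-finite training loss aborts with a diagnostic naming the
  epoch.

## Known limitations

* PNG is the only supported image format (no JPEG decoder among the
  package's dependencies).
* The full-scale head (flattened 336 x 512 tokens into a 1024-wide
  FC) is large (~180M parameters); it builds, but desk-scale
  training uses the width-reduced configurations.
* Parameter counts of published ablation tables cannot be matched
  exactly because the hidden/embedding dimensions they used are not
  published.
* One published dataset-summary value (the 2021 validation average)
  disagrees with its own totals by 0.01 under round-half-up; the
  package keeps correct rounding.

## A worked example

```{r, eval = FALSE}
library(countnet)

gen <- synth_config("ear_field", image_size = 128,
                    count = list(mean = 20, sd = 8, min = 0, max = 45),
                    seed = 100)
spec <- preprocess_spec(size = 128, normalize = "imagenet")
train <- preprocess_samples(synth_samples(200, gen), spec)
gen$seed <- 150; val <- preprocess_samples(synth_samples(50, gen), spec)
gen$seed <- 200; test <- preprocess_samples(synth_samples(50, gen), spec)

model <- countnet_model(input_size = 128,
                        backbone = backbone_config(width = 1 / 16),
                        mpm = mpm_config(slices = c(8, 4), embed_dim = 64,
                                         depth = 2, token_hidden = 32,
                                         channel_hidden = 128),
                        head = head_config(hidden = 128, dropout = 0.2,
                                           k = 16),
                        reduction = 8, seed = 1)
fit <- countnet_fit(model, train, val,
                    countnet_control(epochs = 12, batch_size = 16,
                                     lr = 2e-3, milestones = 9,
                                     gamma = 0.5, seed = 1))
evaluate_counts(fit, test, threshold = 40)
plot(fit)

cam <- compute_cam(fit, test$x[[1]], "mpm8")
```
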