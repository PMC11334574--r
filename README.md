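# countnet

Count-supervised counting networks for dense small objects in field
images — wheat ears in canopy photographs, grains on a table — written
for researchers in plant phenotyping and agricultural image analysis
who want count regression without the cost of box or dot annotation.

Detection-based counters need bounding boxes; density-map counters
need dot annotations. Both are expensive and noisy for overlapping,
elongated objects. `countnet` trains from **per-image totals alone**:
the label for an image with 42 ears is the number 42.

The model is a four-stage regressor:

- a truncated VGG-style **backbone** (first ten 3x3 convolutions,
  three max pools) mapping a 512x512 image to a 512-channel 64x64
  feature map `M_b`;
- **channel + spatial attention** (CBAM): sigmoid gates
  `M_cb = M_c ⊙ M_b`, `M_f = M_s ⊙ M_cb`, with
  `M_c = σ(FC(max_hw M_b) + FC(avg_hw M_b))` and
  `M_s = σ(conv[max_c M_cb ; avg_c M_cb])`;
- a **multiscale perception module**: `M_f` sliced into 16x16, 8x8
  and 4x4 patches (16, 64 and 256 tokens), each scale projected and
  passed through N = 4 MLP-mixer layers, concatenated (336 tokens)
  and mixed again;
- a **counting head**: `x1 = ReLU(FC1(flatten))`,
  `x2 = FC2(Dropout(x1))`, `Ĉ = ReLU(mean(x2))`.

Training uses SGD with momentum on the L1 loss, batch 16, a
multi-step learning-rate schedule, and keeps the checkpoint with the
best validation MAE. Metrics are MAE, RMSE and R², with optional
density stratification (counts ≤ 40 vs > 40). All network arithmetic
— forward and backward — is implemented in the package (im2col + BLAS
convolutions, compiled kernels for the pooling/slicing primitives)
and verified against explicit-loop oracles and finite differences.

A seeded synthetic generator (`synth_config()`, `render_field()`,
`generate_dataset()`) produces ear-field and grain-scatter images
with exact count labels, so every stage is testable without any
dataset download. Gradient-weighted attention heatmaps
(`compute_cam()`) visualize what the backbone and each mixer branch
attend to.

## A worked example

Train a width-reduced model on synthetic ear fields (one CPU, a few
minutes):

```r
library(countnet)

gen <- synth_config("ear_field", image_size = 128,
                    count = list(mean = 20, sd = 8, min = 0, max = 45),
                    seed = 100)
spec  <- preprocess_spec(size = 128, normalize = "imagenet")
train <- preprocess_samples(synth_samples(200, gen), spec)
gen$seed <- 150; val  <- preprocess_samples(synth_samples(50, gen), spec)
gen$seed <- 200; test <- preprocess_samples(synth_samples(50, gen), spec)

model <- countnet_model(input_size = 128,
                        backbone = backbone_config(width = 1 / 16),
                        mpm = mpm_config(slices = c(8, 4), embed_dim = 64,
                                         depth = 2, token_hidden = 32,
                                         channel_hidden = 128),
                        head = head_config(hidden = 128, dropout = 0.2, k = 16),
                        reduction = 8, seed = 1)
print(model)
#> Count-supervised counting network
#>   input 128x128 -> feature map 16x16x32 (stride 8)
#>   attention block: channel (r=8) + spatial (k=7)
#>   perception: slices [8, 4], 20 tokens, d=64, depth N=2, merged
#>   head: hidden 128, dropout 0.20, K=16
#>   parameters: 466,859

fit <- countnet_fit(model, train, val,
                    countnet_control(epochs = 12, batch_size = 16,
                                     lr = 2e-3, milestones = 9,
                                     gamma = 0.5, seed = 1))
evaluate_counts(fit, test)
#> Counting metrics over 50 images:
#>   MAE  2.94
#>   RMSE 3.74
#>   R^2  0.64
```

The MAE of 2.94 means predictions are off by about three ears per
image on scenes averaging twenty; the predict-the-training-mean
baseline sits at MAE 4.73, so the network has learned a real count
signal from totals alone (R² 0.64 of the count variance explained).
Attention maps for any registered layer:

```r
cam <- compute_cam(fit, test$x[[1]], "mpm8")
save_cam(synth_samples(1, gen)$x[[1]], cam, "overlay.png", alpha = 0.5)
```

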