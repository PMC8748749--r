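# mrisr — residual-learning super-resolution for 2D brain MRI slices

`mrisr` reconstructs a high-resolution (HR) 2D brain MRI slice from a
low-resolution (LR) observation. Fast clinical acquisitions (e.g.
single-shot fast spin echo used in fetal imaging) give up in-plane
resolution; super-resolution (SR) recovers part of it computationally.

The package implements the full self-supervised pipeline in R, with no
external data required:

* **Degradation model** — the LR image is derived from the HR slice by
  bicubic decimation, `x = κBy`; bicubic interpolation `z = ux` defines
  the residual `r = y − z` (the detail interpolation loses), so
  `y = z + r` exactly.
* **Network** — a residual-learning CNN: 13 convolutions (3×3, 64
  channels, leaky ReLU slope 0.2) operating at LR resolution feed a 4×4
  stride-2 transposed convolution that emits the residual image, while a
  second 4×4 stride-2 transposed convolution upsamples the input itself;
  the SR output is the sum of the two branches. Forward and backward
  passes are written in R on top of BLAS matrix products.
* **Losses** — robust Charbonnier penalty `ρ(d) = √(d² + ε²)` with
  `ε = 10⁻³` plus a gradient difference loss (GDL) that matches the edge
  magnitudes of prediction and target; combined with unit weights.
* **Training** — SGD with momentum 0.9, weight decay 10⁻⁴, halving
  learning-rate schedule, gradient-norm clipping, random aligned
  128×128/64×64 patch pairs (64×64/32×32 in the desk-scale smoke
  configuration), and the 7:1:1:1 train/weights/hyper/test split.
* **Evaluation** — PSNR and SSIM (11×11 Gaussian window, σ = 1.5)
  with per-subject aggregation and mean/SD/95 % Student-t confidence
  intervals; classical baselines (bicubic, cubic spline, non-local-means
  upsampling with block-mean consistency); error maps; ablation runner.
* **Phantoms** — a seeded generator of brain-like piecewise-smooth
  ellipse images with sharp boundaries and band-limited texture, so the
  entire train → evaluate loop runs on synthetic data.
* **I/O + CLI** — NIfTI volumes (slice extraction with per-volume
  normalization), PNG/TIFF slices, YAML configs, CSV reports, and a CLI
  (`inst/cli/mrisr.R`) with verbs `phantom`, `degrade`, `train`, `sr`,
  `eval`, `ablate`.

## Worked example

Train the network on 20 synthetic phantoms and compare it with classical
interpolation on 5 held-out phantoms (about 4 minutes on one CPU):

```r
library(mrisr)

smoke  <- smoke_config(seed = 1)
train  <- generate_dataset(smoke$n_train, smoke$phantom, seed = 1)
test   <- generate_dataset(smoke$n_test, smoke$phantom,
                           seed = smoke$test_seed)

fit <- train_network(train, smoke$train)
tail(fit$history, 1)          # final epoch: learning rate and loss

report <- evaluate_methods(
  test,
  list(model        = model_method(fit$model),
       bicubic      = sr_method("bicubic"),
       cubic_spline = sr_method("cubic_spline")),
  scale = 2)
report
```

```
   epoch    lr     loss val_psnr
30    29 0.003 20.39994       NA

method         metric      mean       SD                 95% CI
model          psnr    28.5808   0.6716   [ 27.7469,  29.4147]
model          ssim     0.9116   0.0105   [  0.8986,   0.9246]
bicubic        psnr    27.2872   0.5726   [ 26.5762,  27.9982]
bicubic        ssim     0.9435   0.0084   [  0.9331,   0.9539]
cubic_spline   psnr    27.2611   0.5566   [ 26.5700,  27.9522]
cubic_spline   ssim     0.9384   0.0082   [  0.9282,   0.9486]
```

PSNR is `10·log10(1/MSE)` in dB on the `[0, 1]` intensity range (higher
is better; +1 dB ≈ 21 % lower MSE); SSIM is structural similarity in
`[−1, 1]`; the mean/SD/CI rows are computed across the five test
subjects. After 120 SGD steps the model recovers edge detail that
bicubic and spline interpolation lose — the +1.3 dB PSNR gain — while
its SSIM still trails the interpolators: at this short desk-scale
schedule the edge-sharpening loss leaves low-amplitude noise in flat
regions that SSIM penalizes more than PSNR does (see the methods
vignette for the training dynamics).

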