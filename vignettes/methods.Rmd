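---
title: "Residual-learning super-resolution for brain MRI slices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-learning super-resolution for brain MRI slices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisr)
```

## The problem and the model

Fast 2D MRI acquisitions (for example single-shot fast spin echo sequences
used in fetal imaging) trade in-plane resolution for speed and motion
robustness. Single-image super-resolution (SR) tries to recover a
high-resolution (HR) slice $y$ from a low-resolution (LR) observation $x$.
`mrisr` implements the self-supervised formulation in which the LR image is
derived from the HR image by a known degradation,

$$x = \kappa B y, \qquad z = u x, \qquad r = y - z,$$

where $\kappa B$ is bicubic decimation by a factor of 2, $u$ is bicubic
interpolation back to the HR grid, and $r$ is the *residual*: the detail that
interpolation cannot restore. Because $z$ is cheap and already close to $y$,
the network only has to model $r$, which concentrates at tissue boundaries
and in fine texture. This residual decomposition is exact by construction in
`make_pair()` (`hr == upsampled + residual`, bit for bit).

The network (`build_network()`) has two branches that are summed pixelwise:

* a **residual branch**: 13 convolutions (3×3, 64 channels, zero padding so
  feature maps keep the LR size, each followed by a leaky rectifier with
  negative slope 0.2), closed by one 4×4 stride-2 transposed convolution
  mapping the 64 feature channels to a 1-channel residual image at HR size;
* an **image branch**: a single 4×4 stride-2 transposed convolution applied
  to the LR input itself — a learned upsampler of the raw image.

With the image branch enabled the graph contains exactly 13 convolutions and
2 transposed convolutions. The feature branch works entirely at LR
resolution, which is what makes the architecture cheap relative to networks
that first interpolate and then filter at HR resolution.

Training minimizes the combined loss

$$L = L_{\mathrm{Charbonnier}} + \lambda\, L_{\mathrm{GDL}},
\qquad \lambda = 1,$$

with the robust Charbonnier penalty
$\rho(d) = \sqrt{d^2 + \varepsilon^2}$, $\varepsilon = 10^{-3}$, averaged
over pixels, and the gradient difference loss (GDL)
$\sum_{i,j} \big(|\nabla y| - |\nabla \hat y|\big)^2$ summed over
horizontal and vertical neighbor pairs and averaged over batch items. The
Charbonnier term behaves like L2 below $\varepsilon$ and like L1 above it,
bounding the influence of outlier pixels; the GDL term pushes the
prediction's edge magnitudes toward the target's, sharpening
reconstructions, and is blind to constant offsets.

## Reduction conventions

Two reduction choices are deliberately asymmetric and worth stating:

* Charbonnier is a **per-pixel mean** (over all pixels of all batch items),
  so its gradient scale does not change with the patch size and the learning
  rate does not need re-tuning when patches change.
* GDL is a **per-image sum** of squared neighbor-difference discrepancies,
  averaged over batch items only. This matches the plain double-sum
  definition and makes the hand-checkable 2×2 case well defined: for a
  target with one unit edge per row and a flat prediction the loss is
  exactly 2.0.

Because of the sum reduction, the GDL term (and its gradient) grows with the
patch area and numerically dominates the Charbonnier term during training;
the combined loss is used with unit weights nonetheless, and `gdl_weight`
exists to switch the term off for the ablation.

## Numerical and design choices

**Bicubic kernel.** "Bicubic" is implemented as the Keys cubic convolution
kernel with $a = -0.5$, pixel-centers aligned, edge replication at borders.
Decimation is a single bicubic resampling without a separate anti-alias
blur; an optional Gaussian pre-blur flag (`pre_blur_sigma`) exists and
defaults to off.

**Transposed-convolution geometry.** The 4×4/stride-2 transposed
convolutions are computed in polyphase form (each of the four output phases
is a 2×2-tap filter of the input), which guarantees an exactly
$2H \times 2W$ output for any input size. Their input is replicate-padded by
one pixel so that the borders of the learned upsampling behave like the
fixed resamplers; without this the outermost HR rows and columns would be
systematically dimmed by the zero padding, a border artifact that PSNR at
desk image sizes is quite sensitive to.

**Initialization.** Conv layers use seeded He-style initialization scaled
for the leaky slope. The image-branch transposed convolution starts at the
bilinear kernel `(0.25, 0.75, 0.75, 0.25)⊗(…)`, the standard initialization
for learned upsamplers, and the residual-branch transposed convolution
starts at a small scale (gain 0.1), so an untrained network is already a
reasonable interpolator plus a near-zero residual. Training then only has to
learn detail, not upsampling from scratch. A published-weights warm start is
intentionally not used; everything is reproducible from seeds.

**Channel width before upsampling.** The 13th convolution keeps 64
channels and the transposed convolution performs the 64→1 reduction. The
alternative (a 64→1 conv followed by a 1-channel upsampler) is expressible
through `channels` but is not the default, since collapsing to one channel
before upsampling discards most of the learned representation.

**Ablation reading.** "Without the bottom transposed convolution" removes
the image branch entirely: the residual branch output is then read as the
full SR image. This is the reading under which the comparison measures the
value of residual learning rather than of one extra layer.

**Optimizer.** Plain stochastic gradient descent with classical momentum
0.9 and L2 weight decay $10^{-4}$ added to the gradient; the learning rate
is halved every 50 epochs. An *epoch* is defined as `steps_per_epoch` SGD
steps (default 1), each on `batch_size` freshly sampled patches; patch
sampling is uniform with replacement over even HR offsets, so every LR
patch is positionally aligned with its HR patch. The published recipe's
initial rate of $10^{-5}$ presupposes warm-started weights; training from
random initialization at desk scale uses $3\times10^{-3}$ (the
[smoke_config()] value), made safe by global gradient-norm clipping at 10:
the sum-reduced GDL produces early gradients with norms in the hundreds
to thousands, orders of magnitude above their late-training values, and
without clipping no single rate serves both regimes (small rates freeze
the network, large ones diverge).

A dynamic worth knowing: because the GDL term dominates the combined
gradient, short runs first sharpen edges while injecting low-amplitude
noise into flat regions; PSNR only overtakes plain bicubic interpolation
once the Charbonnier term has cleaned the flats, which at the smoke scale
happens after roughly a hundred steps. The 120-step smoke recipe sits
past that crossover; runs a factor of two shorter can score *below*
bicubic while still descending the loss.

## The phantom generator

`generate_phantom()` produces piecewise-smooth ellipse compositions:
uniform background, `n_ellipses` ellipses painted in order (later wins),
drawn uniformly within margins that keep them inside the frame, optional
Gaussian smoothing of the label image, and band-limited texture (smoothed
white noise, rescaled to a peak-to-peak amplitude) added inside the
foreground before clipping to $[0, 1]$.

This emulates exactly the image features the method needs to exercise:
sharp closed boundaries (cortical-ribbon-like nested edges where
interpolation loss concentrates) and recoverable high-frequency texture. It
deliberately does **not** emulate MR physics — no bias fields, no Rician
noise, no partial-volume effects, no anatomy. Passing tests on phantoms
therefore demonstrates that the degradation model, network, losses and
optimizer work as specified and that training recovers detail that
interpolation loses; it does not demonstrate clinical image quality on real
scanner data.

## Evaluation protocol

`evaluate_methods()` follows the self-supervised protocol: each HR slice is
degraded internally, every method reconstructs from the LR image, and
PSNR ($10\log_{10}(1/\mathrm{MSE})$ on the $[0,1]$ range) and SSIM (11×11
Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, valid-mode
statistics) are computed against the original. Slices are averaged per
subject, and subject-level values are summarized as mean, sample SD, and a
two-sided Student-t confidence interval (default 95%). Both aggregation
granularities (per slice, per subject) are retained in the report because
table conventions differ on which n the spread refers to.

Identical images report PSNR `Inf` as the perfect-reconstruction sentinel;
summaries drop non-finite values.

The classical baselines are cubic-spline interpolation (separable natural
splines through the LR samples) and a compact non-local-means upsampling
(NMU): bicubic initialization, then alternating NLM regularization
(3×3 patches, 11×11 search window, Gaussian patch similarity) with a
subsampling-consistency correction that re-imposes the LR block means; the
final correction makes the output's 2×2 block means match the LR input to
numerical precision.

## Desk-scale experiment sizes

The package's built-in experiments are sized for a single CPU: training
smoke runs use 20 phantoms of 128×128, 30 epochs of four batches of
eight 64×64 HR patches (120 SGD steps), with 5 held-out phantoms for
testing; the ablation comparison repeats that run per variant across 3
seeds. These sizes are the
package's reference configuration for demonstrating descent, the benefit of
the learned residual over bicubic interpolation (+0.5 to +1.9 dB PSNR
across seeds), and the directional effect of the GDL and of the image
branch; the ablation claims are directional (majority of seeds) rather
than pointwise. One desk-scale signature to expect: the 120-step model
wins on PSNR but can still trail the fixed interpolators on SSIM, because
residual flat-region noise from the edge-dominated loss costs more under
SSIM's local-structure weighting than under mean-squared error; longer
schedules close that gap as the Charbonnier term smooths the flats.

## Known limitations

* Only scale factor 2 is implemented end-to-end (the transposed-convolution
  engine is specialized to 4×4/stride-2); cascaded ×4/×8 is out of scope.
* The degradation model is isotropic in-plane bicubic decimation; no
  through-plane (slice-thickness) modelling.
* The NMU baseline is a compact rendition of the classical method, not a
  line-by-line port; it is used as a consistency-constrained smoother
  baseline, not as a reference implementation.
* Phantoms are not anatomical and carry no scanner noise model; conclusions
  about real MRI require real volumes (the I/O path accepts NIfTI).
* Training is CPU-bound R; it is meant for desk-scale experiments and
  method verification, not for large-corpus training.
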