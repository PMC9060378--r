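---
title: "Joint image/mask synthesis from a single training pair: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint image/mask synthesis from a single training pair: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medical segmentation datasets are small, expensive to annotate, and often
restricted from sharing.  `segsynth` implements a pipeline that trains a
generative model on a *single* image and its binary segmentation mask and
then synthesizes an unlimited number of new image/mask pairs from it: the
RGB image and the mask are stacked into one four-channel sample, so the
model generates image and annotation *jointly* and every synthetic image
comes with a pixel-exact synthetic ground truth.  A second, optional step
transfers texture ("style") from the real image onto each generated image
to sharpen its realism.  Evaluation machinery (Fréchet distances over deep
features, mask-size statistics) quantifies how close synthetic sets are to
the real data.

## Step 1: the multi-scale single-image GAN

The four-channel sample `x` (channels 1–3 RGB, channel 4 mask, all values
in the model domain `[-1, 1]`) is rescaled into a pyramid
`x_0, …, x_{N-1}` from coarsest to finest.  One generator/critic pair is
trained per scale, coarsest first, each scale frozen when done:

* the coarsest generator maps pure noise to a sample:
  `y_0 = clamp(tanh(net(z_0)))`;
* every finer generator refines the upsampled previous output with a
  learned residual, `y_i = clamp(up(y_{i-1}) + tanh(net(σ_i·z_i +
  up(y_{i-1}))))`.

The critic at each scale is Markovian (a fully convolutional patch critic
whose spatial mean is the score), trained with the Wasserstein objective
`mean D(fake) − mean D(real)` plus a gradient penalty
`gp_weight·(‖∇_x D(x̂)‖ − 1)²` at a random interpolate `x̂`.  The generator
minimizes `−mean D(fake) + α·MSE(reconstruction, x_i)`, where the
reconstruction path uses one fixed noise draw `z*` at the coarsest scale
and zero noise above it; its RMSE against the next level also calibrates
the per-scale noise amplitude `σ_i` (`σ_0 = 1` by convention).  The mask
channel passes through every loss exactly like a color channel — no
special handling — which is what makes the generated mask align with the
generated image.

### Assumptions

* A single image's internal patch statistics are rich enough to learn
  from; diversity across samples comes from noise injected at the coarse
  scales, so generated lesions vary in shape and position but share the
  palette and texture of the training image.
* Masks are strictly binary; the continuous mask channel a generator emits
  is thresholded at the model-domain midpoint 0 (the file-domain midpoint
  128).  The threshold is a convention — no reference value exists — and
  is applied after every resize as well, so pyramid masks stay binary.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scale_factor` | 0.75 | nominal per-level downscale ratio |
| `min_size` / `max_size` | 25 / 250 px | coarsest-level bound / input cap |
| `epochs_per_scale` | 2000 | one epoch = 3 critic + 3 generator updates |
| `lr_g`, `lr_d` | 5e-4 | Adam, betas (0.5, 0.999), ×0.1 at 80 % of epochs |
| `recon_weight` (α) | 10 | reconstruction anchor weight |
| `gp_weight` | 10 | gradient-penalty coefficient |
| `noise_amp_base` | 0.1 | scales per-level RMSE into σ_i |
| `base_channels` | 32 | width at the coarsest scale, ×2 every 4 scales |
| `max_grad_norm` | 50 | global gradient-clip threshold, both networks |

With the defaults, a 250-px input yields a 10-level pyramid.  The level
count comes from `N = 1 + ceil(log(min_size/max_dim)/log(scale_factor))`
and the sizes follow the geometric schedule
`round(dims · (min_size/max_dim)^((N-1-i)/(N-1)))`: the *effective* ratio
is adjusted so the coarsest level lands exactly on `min_size` (≈ 0.774
instead of 0.75 for the defaults).  The naive alternative — iterating
`size ← round(size · 0.75)` until the bound — gives only 9 levels and a
coarsest level below the bound; the adjusted schedule is the convention of
the reference single-image GAN implementation and keeps both the
"10 scales" convention and the `min_size` invariant.

### Numerical and design choices

* **Networks.**  Five conv blocks (3×3), leaky-ReLU slope 0.2.  The input
  is zero-padded once by `n_blocks·(k−1)/2` and all convs are valid, so
  the receptive field at the finest scale stays small (11 px) — the
  patch-statistics property the multi-scale design relies on.  The
  generator head is conv+tanh and zero-initialized, making the generator
  exactly the identity on its prior at initialization (training starts
  from the upsampled coarse reconstruction rather than noise).
* **Normalization.**  Generator blocks use per-channel normalization over
  the spatial dimensions (batch-of-one batch norm) with learned affine
  parameters; statistics are always the current input's, so generation is
  deterministic.  The *critic carries no normalization*: the gradient
  penalty is defined per input, interacts badly with batch statistics, and
  a norm-free critic is piecewise-linear in its input, which lets the
  penalty's parameter gradient be computed exactly by one tangent pass
  (a mask-linearized forward of the scaled input gradient) instead of
  approximate double backprop.  Because the critic is norm-free, the
  penalty weight uses the canonical value 10; the weaker 0.1 sometimes
  paired with batch-normalized critics demonstrably under-constrains a
  norm-free critic (critic scores diverge within tens of epochs).
* **Output bounding.**  `clamp(prior + tanh(residual), -1, 1)` keeps every
  output in the model domain.  The backward pass treats the clamp as the
  identity (straight-through): a hard zero gradient outside the range
  would permanently freeze any pixel that overshoots, since no loss could
  ever pull it back.
* **Gradient clipping.**  Both updates clip the global gradient norm at
  50.  Instrumented smoke runs showed rare adversarial bursts 10–100×
  the typical norm (the 1/sd factor of normalization layers explodes on
  near-constant channels of narrow networks); clipping removes the bursts
  and leaves ordinary updates (norms ≈ 5–40) untouched.
* **Noise layout.**  The coarsest scale draws independent noise per
  channel; finer scales draw one spatial channel broadcast across all
  four.  Generator updates within an epoch reuse the last critic update's
  noise and prior, the reference convention.
* **Divergence.**  Any non-finite loss aborts with the scale and epoch in
  the message.
* **Determinism.**  All randomness flows through R's RNG under the config
  seed; generation saves and restores the caller's RNG state.  Training,
  generation and checkpoint round trips are bit-reproducible on a fixed
  BLAS.

## Step 2: style-transfer refinement

Each generated RGB image (content) is optimized against its real source
image (style) by minimizing `content_weight·D_C + style_weight·D_S`, where
`D_C` is the feature-map MSE at the content taps and `D_S` the Gram-matrix
MSE summed over the style taps (`G = F Fᵀ/(C·H·W)`).  The ratio
"content:style = 1:1000" is read literally as weights 1 and 1000; the
default step count is 1000.  Optimization is box-constrained L-BFGS
(`[-1, 1]`), run one line-search iteration per recorded step so the loss
history is monotone up to line-search tolerance; initialization is the
content image, which preserves the structure the mask describes — the mask
channel itself is never optimized and passes through bit-identically.

The classical feature extractor for this method is an ImageNet-pretrained
VGG network.  Pretrained weights cannot be bundled or downloaded in an
offline installation, so the default backend (`"test"`) is a small
fixed-seed random-weight CNN with taps `conv1…conv4` (content tap
`conv3`, style taps all four).  Random convolutional features preserve
enough texture information for the optimization properties that the tests
assert (fixed points, loss descent, Gram identities); they do *not* make
the refined images perceptually equivalent to VGG-based refinement, and no
test claims they do.

## Evaluation machinery

* `frechet_distance` implements
  `‖μ_a−μ_b‖² + Tr(C_a + C_b − 2(C_a C_b)^{1/2})` with the symmetric
  eigendecomposition route `sqrtm(S_a C_b S_a)`; negative eigenvalues are
  clipped at 0 and rejected beyond a 1e-8 relative tolerance.  Covariances
  use the unbiased (n−1) estimator.
* FID fits one Gaussian per image *set* over pooled features; SIFID fits
  one Gaussian per *image* over per-spatial-location feature vectors and
  averages the per-pair distances.  Repeated generated sets aggregate into
  a report of per-set values, mean and sample SD.
* The deterministic test backend (seeded random CNN, 64×64 input, 16-dim
  features over a 16×16 grid) replaces the Inception backends offline, for
  the same reason as above.  Self-comparisons are numerically zero under
  any backend, which is the identity the evaluation tests pin down.
* Mask statistics: `true_pixel_percentage` is the foreground fraction
  ×100; `percentage_histogram` uses half-open bins `[lo, lo+5)` with the
  last bin closed at 100, so counts are conserved.

## The fixture generator

`make_toy_sample()` draws a textured background (multi-octave smooth
noise, gradients+sinusoids, or blurred speckle), re-textures an elliptical
"lesion" region at a chosen contrast, and emits the exact ellipse
indicator as the mask.  `make_toy_dataset()` samples lesion areas from a
log-normal on the percentage scale (median 8 %, log-sd 0.8, clipped to
[0.5 %, 60 %]), giving the right-skewed size distribution (median < mean)
characteristic of clinical lesion datasets, with random eccentricity,
rotation, position and background type.  What the fixtures do *not*
emulate: specular highlights, vignetting, instrument artifacts, color
calibration of real endoscopy, or ambiguous lesion boundaries.  A green
training test on fixtures therefore establishes that the pipeline learns
and reproduces joint image/mask patch statistics at smoke scale — not
clinical realism.

## Smoke-scale testing profile

The acceptance-level training test runs a 64×64 fixture, 3 pyramid scales
(64/51/40), width 8, 150 epochs per scale — about 5 minutes on one CPU.
Width trades off against the adversarial/reconstruction equilibrium: at
width 8 with 4 scales the finest scale equilibrates before halving its
initial reconstruction error, while 3 scales at width 8 train stably;
wider networks (12–32 channels, the reference regime) also train well but
exceed a 10-minute CPU budget.  Production use should keep the 32-channel
default and the 2000-epoch schedule.

## Known limitations

* Pure-R convolution kernels: a full-scale run (250 px, 10 scales, 2000
  epochs) is orders of magnitude slower than the GPU reference; the
  package is sized for method study and small images, not bulk dataset
  generation.
* No pretrained perceptual backends offline; absolute SIFID/FID values
  are not comparable to published Inception-based numbers.
* Binary masks only; one lesion class.  Multi-class masks would need a
  channel per class and a different binarization rule.
* The style-transfer step refines RGB only and can, at extreme style
  weights, introduce texture inside regions the mask labels background;
  the mask is never adjusted to follow it.
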