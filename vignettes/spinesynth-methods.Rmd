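---
title: "Synthesizing sagittal T1w and STIR spine MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing sagittal T1w and STIR spine MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sagittal T1-weighted fast spin echo (T1w FSE) and short tau inversion
recovery (STIR) sequences are central to assessing vertebral bone marrow:
fat is bright on T1w, while free water (edema, inflammation) is dark on T1w
and bright on STIR. Large epidemiological imaging studies, however, often
acquired only a sagittal T2w FSE plus an axial T1w gradient-echo Dixon
sequence, whose separated fat and water images carry the missing
fat/water information but at a through-plane resolution far too coarse for
sagittal reading. `spinesynth` implements a pipeline that fuses these two
inputs into synthetic sagittal T1w FSE and STIR volumes:

1. **Stage 1** translates (T2w, Dixon-fat, Dixon-water) into a synthetic
   T1w FSE volume on the T2w grid.
2. **Stage 2** translates (T2w, synthetic T1w) into a synthetic STIR.
   The native T1w is never consumed at stage 2, so the chain runs on
   cohorts that lack T1w FSE entirely.

Because the cohort data this pipeline targets are access-restricted, the
package ships a synthetic multi-contrast spine phantom as its test bed
(see below); everything else is agnostic to where the NIfTI volumes come
from.

## Preprocessing and chunk fusion

Volumes are standardized to the RIP orientation (voxel axes increasing
toward Right, Inferior, Posterior) and a sagittal in-plane resolution of
1.1 x 1.1 mm, keeping the native coarse right-left spacing (typically
3-4 mm). Intensities, which are non-negative scanner units with arbitrary
per-run maxima, are rescaled linearly from `[0, max]` to `[-1, 1]`. The
maximum is the global volume maximum; a percentile-based cap was
considered but rejected because the phantom and typical FSE volumes have
no extreme-value tail that would warrant it.

Whole-spine acquisitions arrive as several vertically limited chunks,
each already positioned in world coordinates (chunks follow the spine, so
they are laterally offset in scoliosis). Fusion computes the minimal
world-space bounding box over all chunks, resamples every chunk onto that
grid, and blends overlaps with the weight

$$ w_x \;=\; 1 - \frac{d_x}{\sum_i d_i}, $$

where $d_i$ is the distance from the voxel to the nearest voxel covered
*only* by chunk $i$ (where no interpolation is needed). Two design
points the formula leaves open:

* **Metric.** $d_i$ is the 3D Euclidean distance in voxel units,
  computed with a separable exact distance transform. For vertically
  stacked chunks this reduces to the obvious linear ramp across the
  overlap; for oblique overlap geometries it stays isotropic.
* **More than two chunks.** With $k$ overlapping chunks the raw weights
  sum to $k - 1$; they are renormalized to sum to one. Voxels where all
  $d_i = 0$ receive equal weights.

The axial Dixon stack is typically offset from the T2w frame by a few
voxels. A translation-only registration maximizes normalized
cross-correlation over integer-voxel shifts (FFT-accelerated, with an
optional quadratic sub-voxel refinement); rotations and deformable motion
are deliberately out of scope, since breathing and organ motion cannot be
compensated by a rigid model anyway. A peak NCC below 0.3 (configurable)
flags the registration as failed so such cases can be excluded rather
than silently misaligned.

## The translation network

Both stages use the same fully convolutional 3D residual U-Net, trained
with the Pix2Pix mechanism:

* **Block design.** Residual blocks of 3D convolution, group
  normalization with 8 groups, and SiLU activation; downsampling by 2 per
  level; **addition** (not concatenation) for skip connections, halving
  decoder memory; a single-channel tanh head keeps outputs in `[-1, 1]`.
* **Positional embeddings.** Three extra input channels, each a linear
  gradient from 0 to 1 along one axis *of the original volume frame*
  before random cropping, so the network knows where a training patch
  sits inside the subject. At inference the embeddings are likewise held
  in the original frame while the volume is padded to dimensions
  divisible by 8 (pad value -1 = background).
* **Objective.** The generator minimizes
  $10\,L_1(\hat x, x) + 10\,(1 - \mathrm{SSIM}(\hat x, x)) +
  L_2(D(\hat x), 1)$, i.e. the reconstruction terms are weighted 10:1
  against a least-squares adversarial term from a 3-layer strided
  patch discriminator, which itself minimizes
  $0.5\,L_2(D(\hat x), 0) + 0.5\,L_2(D(x), 1)$.
* **Optimizer.** Adam with betas (0.5, 0.999) (the Pix2Pix convention;
  only the learning rate is prescribed by the recipe), learning rate
  2e-5, batch size 3, training patches of (16, 192, 192) voxels for the
  T1w task and (16, 256, 256) for STIR.
* **Augmentation.** Per-input-channel brightness/contrast jitter with
  factors drawn from [0.8, 1.2], applied on a [0, 1] working scale as
  contrast-about-the-mean followed by brightness scaling, with clamping.
  Targets are never jittered: the augmentation emulates scanner histogram
  variability of the *inputs*, and jittering the regression target would
  make it ambiguous. Training data are additionally replicated three
  times at random sagittal in-plane resolutions between 1.0 and 0.5 mm.

Several details are intentionally package-level decisions where the
recipe is silent: channel widths default to 32 at the finest level,
doubling per level over 4 levels (the contract is the block design, not
the widths, and both are configurable); the SSIM term uses a 7-cubed
uniform window on a [0, 1] rescale of the [-1, 1] tensors (a small window
suits patches only 16 voxels deep); and the notation "SSIM of the
difference" in some descriptions of this objective is implemented as the
SSIM *between* prediction and target, which is the quantity that is 1 at
a perfect reconstruction. The Dixon input enters as both fat and water
channels; a configurable channel subset reproduces the single-input
(T2w-only) ablation.

Every layer's backward pass is written out explicitly (im2col + GEMM
convolutions in single precision, the customary deep-learning precision,
behind an R interface), which keeps training fully deterministic under a
seed: weight initialization, patch offsets, augmentation draws and
shuffling all derive from `train_config(seed = ...)`, and two runs with
the same seed are bit-identical.

## SSIM

`ssim3d()` computes mean local SSIM over all *complete* cubic windows
with the standard constants $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ and
sample-covariance normalization, matching the reference implementation in
scikit-image to which it is cross-checked in the tests. Volumes smaller
than the window fall back to a single global window. The training loss
uses an analytic gradient of this quantity (validated against finite
differences) rather than a surrogate.

## The spine phantom

The phantom generator replaces restricted cohort data with a fully
controlled, seeded test bed. It is schematic by design: stacked cuboid
vertebral bodies separated by discs, a posterior cerebrospinal-fluid
canal and surrounding muscle, each tissue carrying a fat fraction $f$ and
water fraction $w$. Focal lesions (water-rich "modic1"/"edema",
fat-rich "modic2"/"hemangioma") are painted as spheres overriding
$f/w$ inside vertebral bodies. All five contrasts derive from one linear
forward model

$$ s \;=\; \mathrm{base}(\text{label}) + \alpha_m f + \beta_m w +
   \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2), $$

with coefficient signs fixed to the qualitative physics: $\alpha > 0$
for T1w, T2w and Dixon-fat; $\alpha \le 0$ for STIR (fat suppression) and
Dixon-water; $\beta < 0$ for T1w (water dark); $\beta > 0$ for T2w, STIR
and Dixon-water; $\beta \approx 0$ for Dixon-fat. Defaults
(base: vertebra 0.4, disc 0.5, muscle 0.3, canal 0.2, background 0.05;
$\alpha$/$\beta$: T1w +0.5/-0.3, T2w +0.4/+0.5, STIR -0.35/+0.6,
Dixon-fat +0.8/0, Dixon-water -0.1/+0.8) were chosen once as the simplest
values reproducing the fat/water signal behavior the two-stage chain
relies on; they make no claim of Bloch-equation fidelity. The Dixon pair
is degraded along the inferior-superior axis (Gaussian blur with FWHM
equal to an axial slice thickness of 6 mm, decimation, and linear
resampling back) to emulate its poor sagittal resolution. The default
phantom is 32 x 96 x 96 voxels at (3.0, 1.1, 1.1) mm with noise
$\sigma = 0.02$ — desk-scale, but with the same axis conventions,
chunking and intensity pipeline as cohort data.

Because the noise-free forward map $(f, w, \text{label}) \to$ all five
contrasts is closed-form, it doubles as an oracle translator: a trained
network can be scored against the exact target it should produce. What
passing these tests shows is that the pipeline's plumbing, geometry,
losses and optimization are correct and that the network can learn a
deterministic fat/water-driven contrast mapping; it does **not** show
radiological fidelity on real anatomy, scanner artifacts, motion, or
pathology diversity — claims that require the restricted cohort data.

## Desk-scale configuration

The shipped tests and the acceptance script train at desk scale on one
CPU: 8 phantom subjects (6 training, 2 validation), patches of
(16, 64, 64) voxels, 8 base channels over 3 levels, 30 epochs, batch 3,
no resolution replication. At this scale a few hundred optimizer steps
are available, so the toy runs use a learning rate of 2e-3; the
full-scale default of 2e-5 is matched to hundreds of thousands of steps
on cohort data and is kept as the package default in `train_config()`.
Validation L1 is measured on fixed center patches of the held-out
subjects and compared against two reference baselines: predicting the
target's mean, and copying the T2w input channel. A trained toy model
must beat both, and the chained synthetic STIR must render a water-rich
lesion brighter than the surrounding vertebral body (with the same
lesion darker than vertebra on the synthetic T1w) — the sign behavior
that makes the two-stage chain clinically meaningful.

## Reader-study analytics

The Turing-test module summarizes reader studies in which radiologists
label presented images as natively acquired or generated. Per-rater
misclassification rates (false / (false + correct)) are averaged with a
sample standard deviation; rounding is half-up to 2 decimals. Interrater
agreement uses Fleiss kappa over the *rated labels* (real/generated),
not over correctness — agreement on which images look suspicious is the
quantity of interest, and a correctness-based statistic would be a
different measure. The standard error is the classical large-sample
Fleiss variance (the attribution of this formula in the literature is
ambiguous, so the implemented form is unit-tested against a from-scratch
evaluation), the 99% confidence interval uses z = 2.576, and
interpretation bands are 0-0.2 Poor, 0.21-0.4 Fair, 0.41-0.6 Moderate,
0.61-0.8 Good, 0.81-1.0 Very good, with boundaries belonging to the
lower band and negative kappa reported as Poor. Kappa is computed per
modality; the package also ships the published per-rater
misclassification rates of a seven-reader spine study
(`inst/extdata/turing_misclassification_rates.csv`), whose per-modality
means the acceptance suite reproduces. The published +/- spreads are
*not* asserted: they were evidently computed from unrounded per-rater
rates, which the printed table no longer contains. Presentation images
are standardized to 150 x 150 pixels at 1.1 mm per pixel, windowed to
[0, 1].

## Numerical choices and degenerate inputs

* Resampling uses trilinear interpolation by default (nearest for label
  maps, tricubic Catmull-Rom available); coordinates within half a voxel
  of the border are linearly extrapolated from the border pair, so a
  resampled linear ramp round-trips exactly. Single-voxel axes fall back
  to nearest-neighbor sampling.
* Padding uses -1, the background level after intensity rescaling, and
  `pad_to_multiple()` returns a crop record whose inverse is bit-exact.
* An all-zero volume cannot be rescaled (its maximum is undefined) and
  maps to constant -1 with a warning; negative intensities are clipped
  to 0 with a warning.
* Registration of constant (zero-variance) volumes fails explicitly with
  a status message; NCC at the integer peak is recomputed on the
  non-wrapped overlap to avoid FFT wrap-around bias.
* A chunk with no exclusive region (fully shadowed by its neighbors) has
  no defined $d_i$; it receives the grid diagonal as a conservative
  distance. All-category-identical rating tables make chance agreement 1
  and kappa undefined; the result is flagged degenerate instead of
  returning NaN.
* Training aborts with a diagnostic on non-finite gradients rather than
  continuing from a poisoned state.

## Known limitations

The phantom's geometry is schematic; no attempt is made to model
vertebral shape, scanner artifacts, bias fields, or motion. The
registration model is translation-only. The 2D network variants and the
unpaired (CycleGAN) baseline of the broader ablation literature are not
implemented; the only supported ablation is the input-channel subset.
Training at cohort scale (thousands of subjects, large patches, many
epochs) is out of scope for the pure-CPU implementation, which is sized
for desk-scale verification and method development.
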