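---
title: "Contrast-free CT perfusion synthesis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-free CT perfusion synthesis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CT perfusion (CTP) maps — cerebral blood flow (CBF, mL/100 g/min), cerebral
blood volume (CBV, mL/100 g), mean transit time (MTT, s) and time to peak
(TTP, s) — are central to acute stroke triage, but require an iodinated
contrast bolus, a perfusion-capable scanner and dedicated post-processing.
`ctpgan` implements a physiology-informed multitask conditional GAN that
maps plain non-contrast CT (NCCT) slices to all four perfusion maps at
once, together with everything needed to exercise and evaluate it without
patient data: a digital brain-phantom simulator, the preprocessing
pipeline, image-quality metrics, ischemia-severity stratification, and the
statistics of a double-blind reader study.

## Model

**Generator.** A U-Net encoder–decoder with a twist: the first four
encoder stages (4x4 convolutions, stride 2, zero-padding 1, LeakyReLU 0.2)
are *shared* across the four map types, extracting common anatomical
features; each map then owns the remaining encoder stages down to a 1x1x512
bottleneck, and a full skip-connected decoder of transposed convolutions
ending in a Tanh. The Tanh output is affinely mapped from [-1, 1] to [0, 1]
map space and concatenated with the 3-channel NCCT input; a final 1x1
transposed convolution — the physician-in-the-loop (PILO) layer — reduces
this 4-channel tensor to the output map. At inference the PILO
input-channel weights can be rescaled (`pilo_rescale(gen, alpha_perf,
alpha_anat)`) to emphasize hemodynamic versus anatomical content without
retraining; `(1, 1)` is the identity.

**Discriminators.** One 70x70-receptive-field PatchGAN per map type: five
4x4 convolution stages (strides 2,2,2,1,1; widths 64,128,256,512,1) over
the 4-channel pair (NCCT, map), sigmoid patch-probability output. The
receptive field follows the recurrence `RF <- RF + (k-1) * prod(previous
strides)`, giving 70 for this geometry (`receptive_field(patchgan_stages())`).

**Parameter ledger.** Exact layer widths are not derivable from text alone,
so the published parameter totals are treated as the authoritative
constraint. With the standard pix2pix ladder (64–512 capped at 8x base
width), one uniform convention reconciles both totals *exactly*: every
convolution and transposed convolution carries a bias, normalization
layers have no learnable affine parameters, and the PILO layer is a 1x1
transposed convolution with bias. Under this ledger the generator has
209,352,408 trainable parameters and the four discriminators 11,063,044
combined; `parameter_ledger()` reports the block-level counts that sum to
these totals. A 1x1 PILO kernel is the unique choice consistent with the
generator total, which is why it is the default. Because the reconciled
ledger has no affine normalization parameters, the totals cannot decide
*where* normalization layers sit; the package normalizes after every
convolution except the first encoder stage, the 1x1 bottleneck stage
(where per-instance statistics degenerate), the Tanh output stage and the
PILO layer — the convention of comparable encoder–decoder GANs.

**Losses.** The generator minimizes

```
total_G = gan_G + lambda1 * L1 + lambda2 * extrema + lambda3 * multimodal
```

- `gan_G`: non-saturating adversarial term `-mean log D(x, G(x))`,
  averaged over the four map kinds (a `non_saturating = FALSE` flag gives
  the saturating min–max form);
- `L1`: mean absolute error in [0, 1] map space, averaged over pixels and
  map kinds;
- `extrema`: each real map slice is min–max normalized to [-0.5, 0.5] and
  squared, giving weights up to 0.25 on the pixels farthest from the slice
  midrange — exactly the very-high/very-low perfusion pixels that signal
  ischemia. These weights multiply the squared difference between the
  min–max-normalized generated and real slices. Min–max statistics are
  computed per slice within the brain mask (the definition speaks of a
  single map image);
- `multimodal`: the central volume principle links the maps physically as
  CBV = CBF x MTT / 60 (with MTT in seconds). The loss takes the *literal*
  elementwise product of the normalized synthesized CBF and MTT against the
  normalized real CBV, `mean |CBF_hat * MTT_hat - CBV|`. Note that on
  normalized scales this product is not dimensionally the normalized CBV
  (the canonical ranges imply a factor of 3); the loss is kept literal, and
  a `mml_scale` flag exposes the consistency factor for experimentation
  (default 1, i.e. off). The phantom, by contrast, enforces the identity in
  physical units exactly.

Defaults are `lambda1 = 100` (the pix2pix convention), `lambda2 = 100`,
`lambda3 = 10`. Because none of these weights is derivable from first
principles, `calibrate_loss_weights()` reports the component magnitudes on
a freshly initialized model so the auxiliary terms can be scaled to
comparable magnitude with `lambda1 * L1`; on phantom batches that
calibration suggests `lambda3` near 40, the value the package's own
ablation experiment uses (below).

**Training.** Per iteration the four discriminators are updated on one
real and one generated pair each (binary cross-entropy with probabilities
clamped at `eps = 1e-7`), then frozen while the generator takes one Adam
step on the combined objective — a strict 1:1 alternation. Adam uses
`beta1 = 0.5`, `beta2 = 0.999`, constant learning rate `1e-4` for both
networks (no decay), batch size 8, 50 epochs at full scale. Batch
normalization is used when the batch has more than one sample, instance
normalization otherwise; normalization always uses current-batch
statistics (no running averages are maintained), which keeps training
fully deterministic for a fixed seed and makes inference statistics
explicit. After each epoch the generator objective is recorded on a
held-out validation split drawn at the image level (100 slices at full
scale). Weight initialization is zero-mean Gaussian with sd 0.02.

## Preprocessing

Order of operations (several published steps are order-ambiguous; this is
the package's resolution): HU windowing (center 40 HU, width 80 HU, to
[0, 1]) -> threshold-morphology skull stripping (largest 4-connected
component strictly inside the display window, holes filled; applied
multiplicatively) -> bilinear resize to the network size (nearest for
masks; pixel-center-aligned so resizing is idempotent and mean-preserving
on integer downsampling) -> pseudo-RGB stacking of the slices at -4 mm /
0 / +4 mm (offset rounded to whole slices; boundary slices are rejected,
never padded) -> perfusion-map normalization by the canonical physiological
ranges CBF [0, 60], CBV [0, 4], MTT [0, 12], TTP [0, 25] -> static
augmentation. Windowing precedes stripping so the bone threshold is
scanner-independent; augmentation operates on normalized data so the
out-of-frame fill value 0 stays meaningful.

Augmentation draws one transform per emitted copy — horizontal flip with
probability 0.5, rotation uniform in +/-10 degrees, integer translations
uniform in +/-30 px per axis — and applies it identically to all seven
channels (3 NCCT + 4 maps) and the mask (bilinear / nearest). The
translation range is a 256-px-scale quantity; the scaled-down test
configurations shrink it proportionally (+/-8 px at 64 px, +/-4 px at
32 px). Two normalizations coexist deliberately: [0, 1] map space is the
stored representation, while z-scoring with training-pool statistics is
applied only at the NCCT input boundary (`standardize_ncct()`).

## The phantom

The simulator emulates the statistical structure the network and the
evaluation assume: an elliptical brain (gray/white matter, CSF ventricles)
inside a high-HU skull ring and air background, replicated across slices
with a slow axial shrink so pseudo-RGB triplets carry real through-plane
context; four perfusion maps obeying CBV = CBF x MTT / 60 exactly before
noise; elliptical ischemic lesions with a core (CBF below a fraction
< 0.30 of baseline, reduced CBV, elevated MTT/TTP) strictly inside a
penumbra (TTP delayed by more than 6 s, preserved CBV); optional NCCT
hypodensity in the core (0 emulates CT-occult early stroke); additive
Gaussian HU noise and multiplicative log-normal perfusion noise
(positivity-preserving).

Baselines are not published for the study cohort, so they were chosen once
from standard physiology inside the normalization ranges and are
configurable: gray matter CBF 50 mL/100 g/min, MTT 4 s, TTP 8 s; white
matter CBF 22, MTT 4.8 s, TTP 9 s; CSF nearly unperfused. Lesion perfusion
is derived *multiplicatively* from the local baseline, so the relative-CBF
core criterion (core CBF < 30% of the mirrored contralateral value, the
mirror being the left–right reflection about the brain midline) holds
whatever tissue the lesion covers, and the core MTT factor is derived as
`core_cbv_fraction / core_cbf_fraction` so the central volume identity
stays exact. Severity labels are never free: they are computed from the
stored masks through the same `mismatch_ratio()`/`classify_severity()`
path used for evaluation (core/penumbra voxel ratio; 0 = none, (0, 0.5] =
mild/moderate, > 0.5 = severe).

What the phantom does *not* emulate: real anatomy (no atlas), contrast
bolus dynamics or deconvolution, scanner artifacts, registration error
between NCCT and CTP, or the texture statistics of real parenchyma. Tests
passing on phantoms therefore demonstrate the correctness of the pipeline
and the learnability of a physiologically structured mapping — not
clinical performance.

## Evaluation

SSIM and UQI are computed inside the tight bounding box of the brain mask,
so background agreement cannot inflate scores. The published formulas give
no window convention; following the metrics' original publications, SSIM
uses an 11x11 Gaussian window (sigma 1.5) with `c1 = (0.01 L)^2`,
`c2 = (0.03 L)^2`, `L = 1` in normalized map space, and UQI uses an 8x8
uniform sliding window with zero stabilizers (windows where both patches
are constant contribute 1 when the means agree, 0 otherwise). All window
parameters are arguments. Severity stratification uses the stored phantom
masks; for real data `derive_ischemia_masks()` applies the relative
thresholds (CBF < 30% of the mirrored contralateral, TTP delay > 6 s over
contralateral) as a commercial-software surrogate.

## Reader-agreement statistics

`build_trials()` realizes the double-blind design: the real and synthetic
map sets of one case always land in different trials, each trial is
shuffled independently and pseudo-anonymized, and the unblinding key is
returned separately. Percent agreement comes with a Wilson score interval;
Cohen's kappa with the Fleiss–Cohen–Everitt delta-method interval (a
seeded case-resampling bootstrap is available as a cross-check). Tables
where both raters are constant have chance agreement 1; kappa is defined
as 0 there, matching the convention that near-constant response
distributions yield kappa 0 despite high raw agreement. `kappa_power()`
simulates paired responses from the joint distribution
`P = (1 - kappa) p p' + kappa diag(p)` — whose population kappa is exactly
the requested value — and tests `kappa = 0` with the Fleiss z-test;
marginals are a required argument because the published power analysis did
not state its inputs.

## Numerical choices and degenerate inputs

- Probabilities are clamped to `[eps, 1 - eps]` before logs; clamped
  values receive zero gradient.
- Min–max normalizations guard constant inputs: a constant real map gives
  an all-zero extrema weight map with a warning; a constant generated map
  contributes through a zero normalized image. Ties in min/max take the
  first index; the extrema gradient includes the dependence on the
  arg-min/arg-max pixels and is finite-difference-verified in the tests.
- Generator outputs are clamped to [0, 1] before denormalization to
  physical units at inference, so predicted volumes always respect the
  canonical ranges.
- `infer_volume()` skips boundary slices without both +/-offset neighbors
  (reported in the `skipped` attribute) and falls back to a full-frame
  mask with a warning when skull stripping finds no tissue (an all-zero
  volume still yields finite maps); during training-set construction such
  slices are an error instead.
- An empty penumbra with an empty core is ratio 0 (severity none); a
  positive core over an empty penumbra is +Inf (severe).

## Problem sizes used by the test suite

Full-scale settings (256x256, base width 64, 50 epochs, batch 8) remain
the configuration defaults. The test suite exercises the complete training
loop at reduced scale, chosen so that the entire suite runs on a single
CPU: the training smoke run uses 64x64 inputs, base width 16, 200
augmented phantom slices and 5 epochs, and asserts that held-out L1 falls
strictly below its value at initialization; the multimodal-loss ablation
uses 32x32 inputs, base width 8, 108 slices and 6 epochs, comparing the
median held-out central-volume residual across five paired seeds with
`lambda3 = 40` (the magnitude-matched calibration above) against
`lambda3 = 0`. At these scales the published full-scale SSIM/UQI ablation
values are not reproducible — they require the original patient cohort —
so the directional property replaces them.

## Known limitations

- No running normalization statistics: models trained with batch
  normalization should be applied to batches of comparable size.
- The multimodal loss is literal on normalized maps (see above); whether a
  dimensional consistency factor would help is an open experimental
  question exposed via `mml_scale`.
- Skull stripping is a threshold-morphology baseline adequate for phantoms
  and clean head CT; it is not a learning-based brain extractor.
- Real-data ingestion is NIfTI-only; DICOM series should be converted
  upstream.
- The GAN training loop is single-device and CPU-oriented at test scale;
  full-scale training is computationally serious and was designed for
  accelerator hardware in the original setting.
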