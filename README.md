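# ctpgan

Physiology-informed multitask GAN for contrast-free CT perfusion map
synthesis, in R.

CT perfusion (CTP) parametric maps — CBF (mL/100 g/min), CBV (mL/100 g),
MTT (s) and TTP (s) — drive acute stroke triage but require an iodinated
contrast bolus and a perfusion-capable scanner. `ctpgan` implements a
conditional image-to-image GAN that synthesizes all four maps at once from
plain non-contrast CT (NCCT) slices, for researchers studying contrast-free
perfusion imaging and for method developers who need a fully testable
reference implementation.

The core pieces:

- **Multitask U-Net generator** — four encoder stages shared across map
  types, then per-map encoders to a 1x1x512 bottleneck, skip-connected
  decoders, and a tunable physician-in-the-loop (**PILO**) 1x1 output layer
  whose input-channel weights can be rescaled at inference
  (`pilo_rescale`) to trade hemodynamic against anatomical content.
  209,352,408 trainable parameters at the default 256x256 configuration.
- **Four 70x70 PatchGAN discriminators** (11,063,044 parameters combined)
  over (NCCT, map) pairs.
- **Physiology-informed objective**:
  `total_G = gan_G + lambda1*L1 + lambda2*extrema + lambda3*multimodal`,
  where the extrema term up-weights pixels far from the slice midrange
  (candidate ischemia) and the multimodal term enforces the central volume
  principle (CBV = CBF x MTT) on the synthesized maps.
- **Digital brain phantom** (`make_phantom`, `sample_cohort`) — paired
  NCCT + perfusion volumes with core/penumbra lesions, the exact
  central-volume identity, and severity labels, so the whole pipeline is
  testable without patient data.
- **Preprocessing** — HU windowing (40/80), skull stripping, pseudo-RGB
  stacking at a 4 mm offset, canonical map normalization, paired static
  augmentation.
- **Evaluation** — SSIM / UQI inside the brain bounding box, and
  ischemia-severity stratification by the core-to-penumbra mismatch ratio
  (0 = none, (0, 0.5] = mild/moderate, > 0.5 = severe).
- **Reader-study statistics** — blinded two-trial randomization, percent
  agreement with Wilson intervals, Cohen's kappa with delta-method or
  bootstrap CIs, and a Monte-Carlo kappa power check.

The CNN stack (convolution, transposed convolution, batch/instance
normalization, Adam, full backpropagation) is implemented in the package
itself with RcppArmadillo kernels; gradients are verified against finite
differences in the test suite.

## Worked example

Train a small model on synthetic cases and score a synthesized volume
(the full-scale defaults are 256x256 / base width 64 / 50 epochs; this
demonstration uses a reduced configuration that runs in about a minute on
one CPU):

```r
library(ctpgan)

cohort <- sample_cohort(
  n = 12, class_mix = c(none = 0.62, mild_moderate = 0.17, severe = 0.21),
  seed = 42,
  spec = phantom_spec(image_size = 64, slice_count = 3, axial_spacing = 4))

tset <- build_training_set(
  cohort, aug_spec(rotation_range = 10, translation_range = 8,
                   copies_per_slice = 4), seed = 1)

fit <- ctp_train(tset, train_config(
  epochs = 3, batch_size = 8, val_size = 8, seed = 1,
  network = network_config(image_size = 64, base_width = 16)))
print(fit)
#> Multitask NCCT-to-CTP GAN fit
#>   image size 64, base width 16, 6 encoder stages (4 shared)
#>   generator parameters: 6,796,744; discriminators (x4): 701,380
#>   trained 3 epochs; validation L1 0.2884 -> 0.2847

p <- cohort[[1]]
vols <- infer_volume(fit, p$ncct, spacing = 4)       # 4 mm pseudo-RGB offset
report <- evaluate_cohort(setNames(list(as_predicted(vols)), p$case_id),
                          list(p))
report
#>    case_id map_kind          ssim          uqi     ratio      severity
#>  case_0001      cbf -0.0002626537 -0.001303084 0.3892617 mild_moderate
#>  case_0001      cbv  0.0307369318  0.014099964 0.3892617 mild_moderate
#>  case_0001      mtt  0.1071824620  0.018968843 0.3892617 mild_moderate
#>  case_0001      ttp -0.0030162983 -0.025248614 0.3892617 mild_moderate
```

The validation L1 falls during training (0.2884 to 0.2847 after three
epochs); SSIM/UQI near zero simply say that three epochs at toy scale are
nowhere near convergence — the metrics, mismatch ratio (0.389) and severity
stratum come straight from the evaluation pipeline. The test suite's
training smoke run (5 epochs, 200 slices) asserts the held-out L1 decrease,
and the ablation test shows the multimodal loss reducing the central-volume
residual of the synthesized maps.

Reader-agreement statistics work on any paired categorical responses:

```r
m <- matrix(c(40, 10, 10, 40), 2)        # 2x2 contingency table, n = 100
unlist(cohens_kappa(m)[c("kappa", "ci")])
#>     kappa       ci1       ci2
#> 0.6000000 0.4432029 0.7567971
kappa_power(0.35, marginals = rep(1/3, 3), n = 140, reps = 2000, seed = 1)
#> [1] 1
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/ctpgan-cli.R` (`phantom`, `train`, `generate`, `evaluate`
subcommands).

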