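# Digital brain phantom: paired NCCT (Hounsfield units) and perfusion-map
# volumes with ischemic core/penumbra lesions, used as a fully synthetic
# stand-in for patient NCCT/CTP pairs. Geometry is a 2D elliptical brain
# (skull ring, gray/white matter, CSF ventricles) replicated across slices
# with a slow axial shrink so that pseudo-RGB slice triplets carry real
# through-plane context. The central volume principle CBV = CBF * MTT / 60
# (CBF in mL/100g/min, MTT in seconds, CBV in mL/100g) holds exactly by
# construction before noise.

#' Canonical physiological normalization ranges of the four perfusion maps
#'
#' CBF [0, 60] mL/100g/min; CBV [0, 4] mL/100g; MTT [0, 12] s;
#' TTP [0, 25] s.
#'
#' @return named list of (lo, hi) vectors
#' @export
map_ranges <- function() {
  list(cbf = c(0, 60), cbv = c(0, 4), mtt = c(0, 12), ttp = c(0, 25))
}

#' Default tissue parameters for the phantom
#'
#' Hounsfield means and normal-tissue perfusion baselines (gray matter
#' perfuses roughly twice as fast as white matter; CSF is nearly
#' unperfused). All baselines sit inside the canonical normalization
#' ranges.
#'
#' @return nested list of per-tissue parameters
#' @export
phantom_tissues <- function() {
  list(gray = list(hu = 38, hu_sd = 0, cbf = 50, mtt = 4.0, ttp = 8),
       white = list(hu = 30, hu_sd = 0, cbf = 22, mtt = 4.8, ttp = 9),
       csf = list(hu = 8, hu_sd = 0, cbf = 6, mtt = 4.0, ttp = 8),
       skull_hu = 1800, air_hu = -1000)
}

#' Lesion specification
#'
#' An elliptical ischemic penumbra with a strictly interior elliptical
#' infarct core. Perfusion inside the lesion is derived multiplicatively
#' from the local baseline, so the relative-CBF core criterion holds
#' against the mirrored contralateral tissue whatever that tissue is.
#'
#' @param center (row, col) pixel coordinates of the lesion center
#' @param core_axes,penumbra_axes (row, col) pixel semi-axes; the core must
#'   be strictly inside the penumbra
#' @param core_cbf_fraction core CBF as a fraction of the local baseline
#'   (must be < 0.30, the relative-CBF infarct-core criterion)
#' @param penumbra_ttp_delay TTP delay in seconds added inside the
#'   penumbra (must exceed 6 s, the delay criterion for tissue at risk)
#' @param core_cbv_fraction core CBV as a fraction of baseline; the core
#'   MTT elevation factor is `core_cbv_fraction / core_cbf_fraction` so the
#'   central volume principle stays exact
#' @param ncct_hypodensity HU decrement applied in the core on NCCT (0
#'   emulates CT-occult early infarction)
#' @return a `ctpgan_lesion` list
#' @export
lesion_spec <- function(center, core_axes, penumbra_axes,
                        core_cbf_fraction = 0.2, penumbra_ttp_delay = 8,
                        core_cbv_fraction = 0.42, ncct_hypodensity = 0) {
  if (any(core_axes >= penumbra_axes)) {
    stop("core axes must be strictly smaller than penumbra axes")
  }
  if (core_cbf_fraction <= 0 || core_cbf_fraction >= 0.30) {
    stop("core_cbf_fraction must be in (0, 0.30)")
  }
  if (penumbra_ttp_delay <= 6) stop("penumbra_ttp_delay must exceed 6 s")
  structure(list(center = center, core_axes = core_axes,
                 penumbra_axes = penumbra_axes,
                 core_cbf_fraction = core_cbf_fraction,
                 penumbra_ttp_delay = penumbra_ttp_delay,
                 core_cbv_fraction = core_cbv_fraction,
                 ncct_hypodensity = ncct_hypodensity),
            class = "ctpgan_lesion")
}

#' Phantom specification
#'
#' @param image_size pixels per side
#' @param slice_count number of axial slices
#' @param axial_spacing slice spacing in mm (the NCCT grid)
#' @param tissue_params see [phantom_tissues()]
#' @param lesion optional [lesion_spec()]
#' @param noise_sd additive Gaussian NCCT noise, HU
#' @param map_noise_sd multiplicative log-normal noise sd on the perfusion
#'   maps (fraction; keeps values positive)
#' @param seed generation seed
#' @return a `ctpgan_phantom_spec` list
#' @export
phantom_spec <- function(image_size = 256, slice_count = 11,
                         axial_spacing = 1, tissue_params = phantom_tissues(),
                         lesion = NULL, noise_sd = 2, map_noise_sd = 0.03,
                         seed = 1) {
  rg <- map_ranges()
  for (t in c("gray", "white", "csf")) {
    tp <- tissue_params[[t]]
    cbv <- tp$cbf * tp$mtt / 60
    if (tp$cbf < rg$cbf[1] || tp$cbf > rg$cbf[2] ||
        tp$mtt < rg$mtt[1] || tp$mtt > rg$mtt[2] ||
        tp$ttp < rg$ttp[1] || tp$ttp > rg$ttp[2] ||
        cbv < rg$cbv[1] || cbv > rg$cbv[2]) {
      stop("tissue baseline outside the canonical normalization ranges: ", t)
    }
  }
  structure(list(image_size = as.integer(image_size),
                 slice_count = as.integer(slice_count),
                 axial_spacing = axial_spacing,
                 tissue_params = tissue_params, lesion = lesion,
                 noise_sd = noise_sd, map_noise_sd = map_noise_sd,
                 seed = as.integer(seed)),
            class = "ctpgan_phantom_spec")
}

inside_ellipse <- function(rows, cols, center, axes) {
  outer((rows - center[1])^2 / axes[1]^2, (cols - center[2])^2 / axes[2]^2,
        "+") <= 1
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()]
#' @param case_id identifier stored with the case
#' @return a `ctpgan_phantom` list: `ncct` (HU volume, dim size x size x
#'   slices), `cbf`, `cbv`, `mtt`, `ttp` (physical-unit volumes, zero
#'   outside the brain), `core_mask`, `penumbra_mask`, `brain_mask`
#'   (logical volumes), `severity`, `seed`, `spacing`
#' @export
make_phantom <- function(spec = phantom_spec(), case_id = "case") {
  stopifnot(inherits(spec, "ctpgan_phantom_spec"))
  n <- spec$image_size
  nz <- spec$slice_count
  tp <- spec$tissue_params
  rows <- seq_len(n); cols <- seq_len(n)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  zc <- (nz + 1) / 2
  skull_px <- max(2, round(n / 36))

  vol <- function() array(0, dim = c(n, n, nz))
  ncct <- vol(); cbf <- vol(); cbv <- vol(); mtt <- vol(); ttp <- vol()
  brain <- core <- penum <- array(FALSE, dim = c(n, n, nz))

  with_seed(spec$seed, {
    for (z in seq_len(nz)) {
      scale <- 1 - 0.12 * ((z - zc) / max(zc, 1))^2
      ax_brain <- c(0.44, 0.38) * n * scale
      ax_skull <- ax_brain + skull_px
      b <- inside_ellipse(rows, cols, ctr, ax_brain)
      sk <- inside_ellipse(rows, cols, ctr, ax_skull) & !b
      wht <- inside_ellipse(rows, cols, ctr, 0.60 * ax_brain) & b
      vent <- (inside_ellipse(rows, cols, ctr + c(0, -0.05 * n),
                              c(0.12, 0.035) * n) |
               inside_ellipse(rows, cols, ctr + c(0, 0.05 * n),
                              c(0.12, 0.035) * n)) & b

      hu <- matrix(tp$air_hu, n, n)
      hu[sk] <- tp$skull_hu
      hu[b] <- tp$gray$hu
      hu[wht] <- tp$white$hu
      hu[vent] <- tp$csf$hu

      f_cbf <- matrix(0, n, n); f_mtt <- matrix(0, n, n)
      f_ttp <- matrix(0, n, n)
      for (nmtis in list(c("gray", "b"), c("white", "wht"),
                         c("csf", "vent"))) {
        msk <- switch(nmtis[2], b = b, wht = wht, vent = vent)
        ti <- tp[[nmtis[1]]]
        f_cbf[msk] <- ti$cbf; f_mtt[msk] <- ti$mtt; f_ttp[msk] <- ti$ttp
        if (ti$hu_sd > 0) {
          hu[msk] <- hu[msk] + stats::rnorm(sum(msk), 0, ti$hu_sd)
        }
      }

      if (!is.null(spec$lesion)) {
        le <- spec$lesion
        pm <- inside_ellipse(rows, cols, le$center, le$penumbra_axes)
        cm <- inside_ellipse(rows, cols, le$center, le$core_axes)
        if (any(pm & !b)) {
          stop("lesion geometry outside the brain mask (slice ", z, ")")
        }
        ring <- pm & !cm
        # penumbra: delayed TTP, mildly reduced CBF, preserved CBV
        f_ttp[ring] <- f_ttp[ring] + le$penumbra_ttp_delay
        f_cbf[ring] <- f_cbf[ring] * 0.80
        f_mtt[ring] <- f_mtt[ring] * (0.95 / 0.80)   # keeps CBV at 0.95x
        # core: severely reduced CBF, reduced CBV, elevated MTT/TTP
        f_cbf[cm] <- f_cbf[cm] * le$core_cbf_fraction
        f_mtt[cm] <- f_mtt[cm] * (le$core_cbv_fraction / le$core_cbf_fraction)
        f_ttp[cm] <- f_ttp[cm] + le$penumbra_ttp_delay + 3
        hu[cm] <- hu[cm] - le$ncct_hypodensity
        core[, , z] <- cm
        penum[, , z] <- pm
      }

      if (spec$noise_sd > 0) {
        hu <- hu + stats::rnorm(n * n, 0, spec$noise_sd)
      }
      f_cbv <- f_cbf * f_mtt / 60
      if (spec$map_noise_sd > 0) {
        f_cbf <- f_cbf * exp(stats::rnorm(n * n, 0, spec$map_noise_sd))
        f_mtt <- f_mtt * exp(stats::rnorm(n * n, 0, spec$map_noise_sd))
        f_ttp <- f_ttp * exp(stats::rnorm(n * n, 0, spec$map_noise_sd))
        f_cbv <- f_cbv * exp(stats::rnorm(n * n, 0, spec$map_noise_sd))
      }
      rg <- map_ranges()
      f_cbf <- pmin(pmax(f_cbf, rg$cbf[1]), rg$cbf[2])
      f_cbv <- pmin(pmax(f_cbv, rg$cbv[1]), rg$cbv[2])
      f_mtt <- pmin(pmax(f_mtt, rg$mtt[1]), rg$mtt[2])
      f_ttp <- pmin(pmax(f_ttp, rg$ttp[1]), rg$ttp[2])
      f_cbf[!b] <- 0; f_cbv[!b] <- 0; f_mtt[!b] <- 0; f_ttp[!b] <- 0

      ncct[, , z] <- hu
      cbf[, , z] <- f_cbf; cbv[, , z] <- f_cbv
      mtt[, , z] <- f_mtt; ttp[, , z] <- f_ttp
      brain[, , z] <- b
    }
  })

  severity <- classify_severity(mismatch_ratio(core, penum))
  structure(list(case_id = case_id, ncct = ncct, cbf = cbf, cbv = cbv,
                 mtt = mtt, ttp = ttp, core_mask = core,
                 penumbra_mask = penum, brain_mask = brain,
                 severity = severity, seed = spec$seed,
                 spacing = spec$axial_spacing, spec = spec),
            class = "ctpgan_phantom")
}

# lesion geometry targeting a severity class, drawn from the current RNG
random_lesion <- function(severity, n) {
  ratio <- switch(severity,
                  mild_moderate = stats::runif(1, 0.15, 0.40),
                  severe = stats::runif(1, 0.60, 0.85),
                  stop("no lesion for severity 'none'"))
  pen <- c(stats::runif(1, 0.08, 0.12), stats::runif(1, 0.07, 0.10)) * n
  side <- sample(c(-1, 1), 1)
  center <- c((n + 1) / 2 + stats::runif(1, -0.03, 0.03) * n,
              (n + 1) / 2 + side * stats::runif(1, 0.19, 0.22) * n)
  lesion_spec(center = center, core_axes = sqrt(ratio) * pen,
              penumbra_axes = pen,
              core_cbf_fraction = stats::runif(1, 0.15, 0.25),
              penumbra_ttp_delay = stats::runif(1, 7, 9),
              core_cbv_fraction = stats::runif(1, 0.38, 0.48),
              ncct_hypodensity = sample(c(0, 0, 2), 1))
}

#' Sample a phantom cohort with a given severity mix
#'
#' @param n number of cases (> 0)
#' @param class_mix proportions over (none, mild_moderate, severe); must
#'   sum to 1
#' @param seed cohort seed; per-case seeds are derived from it, so two
#'   calls with the same seed are identical
#' @param spec template [phantom_spec()] (its lesion/seed fields are
#'   overridden per case)
#' @return list of `ctpgan_phantom` cases
#' @export
sample_cohort <- function(n, class_mix = c(none = 0.62, mild_moderate = 0.17,
                                           severe = 0.21),
                          seed = 1, spec = phantom_spec()) {
  if (n <= 0) stop("n must be positive")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  labels <- c("none", "mild_moderate", "severe")
  if (is.null(names(class_mix))) names(class_mix) <- labels
  with_seed(seed, {
    classes <- sample(labels, n, replace = TRUE, prob = class_mix[labels])
    case_seeds <- sample.int(2^31 - 2, n)
    lapply(seq_len(n), function(i) {
      sp <- spec
      sp$seed <- case_seeds[i]
      if (classes[i] != "none") {
        sp$lesion <- with_seed(case_seeds[i],
                               random_lesion(classes[i], sp$image_size))
      } else {
        sp$lesion <- NULL
      }
      make_phantom(sp, case_id = sprintf("case_%04d", i))
    })
  })
}

#' Cohort manifest
#'
#' @param cases list of `ctpgan_phantom`
#' @return data.frame with case id, seed and severity
#' @export
cohort_manifest <- function(cases) {
  data.frame(case_id = vapply(cases, function(x) x$case_id, character(1)),
             seed = vapply(cases, function(x) x$seed, numeric(1)),
             severity = vapply(cases, function(x) as.character(x$severity),
                               character(1)))
}

#' Write a phantom case to disk
#'
#' One NIfTI volume per map (affine encoding the axial spacing), plus a
#' single serialized bundle of the whole case.
#'
#' @param case a `ctpgan_phantom`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(vol, nm) {
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(1, 1, case$spacing)
    RNifti::writeNifti(img, file.path(dir,
                                      paste0(case$case_id, "_", nm,
                                             ".nii.gz")))
  }
  for (nm in c("ncct", "cbf", "cbv", "mtt", "ttp")) {
    write_one(case[[nm]], nm)
  }
  for (nm in c("core_mask", "penumbra_mask", "brain_mask")) {
    write_one(case[[nm]] * 1, nm)
  }
  saveRDS(case, file.path(dir, paste0(case$case_id, "_bundle.rds")),
          compress = "gzip")
  invisible(dir)
}
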