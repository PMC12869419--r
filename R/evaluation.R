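# Image-quality evaluation (windowed SSIM and UQI inside a brain bounding
# box) and ischemia-severity stratification by the core-to-penumbra
# mismatch ratio.

#' Tight bounding box of a brain mask
#'
#' @param brain_mask logical matrix (nonempty)
#' @return list with `row` = c(first, last) and `col` = c(first, last)
#' @export
brain_bounding_box <- function(brain_mask) {
  if (!any(brain_mask)) stop("empty brain mask")
  rr <- range(which(rowSums(brain_mask) > 0))
  cc <- range(which(colSums(brain_mask) > 0))
  list(row = rr, col = cc)
}

#' Crop an image to a bounding box
#'
#' @param img matrix
#' @param box a [brain_bounding_box()]
#' @return cropped matrix
#' @export
crop_to_box <- function(img, box) {
  img[box$row[1]:box$row[2], box$col[1]:box$col[2], drop = FALSE]
}

gaussian_kernel_1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-mode separable 2D filtering via banded matrices
filter_valid <- function(img, k) {
  n <- length(k)
  band <- function(dim_in) {
    out <- dim_in - n + 1
    A <- matrix(0, out, dim_in)
    for (i in seq_len(out)) A[i, i:(i + n - 1)] <- k
    A
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Structural similarity index (SSIM)
#'
#' Local luminance/contrast/structure comparison in sliding windows
#' (Gaussian 11x11, sigma 1.5 by default), averaged over window positions.
#' Stabilizers default to `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with dynamic
#' range `L = 1` (normalized map space).
#'
#' @param x,y images of the same size (cropped to the brain bounding box
#'   upstream)
#' @param window "gaussian" or "uniform"
#' @param size window side; images must be at least this large
#' @param sigma Gaussian window sd
#' @param L dynamic range
#' @param c1,c2 stabilizing constants
#' @return scalar in [-1, 1]
#' @export
ssim <- function(x, y, window = c("gaussian", "uniform"), size = 11,
                 sigma = 1.5, L = 1, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2) {
  window <- match.arg(window)
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (any(dim(x) < size)) stop("image smaller than the metric window")
  k <- if (window == "gaussian") gaussian_kernel_1d(size, sigma)
       else rep(1 / size, size)
  mx <- filter_valid(x, k); my <- filter_valid(y, k)
  vx <- filter_valid(x^2, k) - mx^2
  vy <- filter_valid(y^2, k) - my^2
  cxy <- filter_valid(x * y, k) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Universal quality index (UQI)
#'
#' SSIM with zero stabilizing constants, evaluated in uniform sliding
#' windows (8x8 by default). Windows where both patches are constant
#' contribute 1 when the means agree and 0 otherwise.
#'
#' @param x,y images of the same size
#' @param size uniform window side
#' @param eps degeneracy threshold for the guarded denominators
#' @return scalar in [-1, 1]
#' @export
uqi <- function(x, y, size = 8, eps = 1e-12) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (any(dim(x) < size)) stop("image smaller than the metric window")
  k <- rep(1 / size, size)
  mx <- filter_valid(x, k); my <- filter_valid(y, k)
  vx <- filter_valid(x^2, k) - mx^2
  vy <- filter_valid(y^2, k) - my^2
  cxy <- filter_valid(x * y, k) - mx * my
  lum <- ifelse(mx^2 + my^2 < eps, 1, 2 * mx * my / (mx^2 + my^2))
  str <- ifelse(vx + vy < eps,
                ifelse((mx - my)^2 < eps, 1, 0),
                2 * cxy / (vx + vy))
  mean(lum * str)
}

#' Core-to-penumbra mismatch ratio
#'
#' Core voxels divided by penumbra voxels, summed over all axial slices.
#' 0/0 is 0; a positive core with an empty penumbra is +Inf (classified
#' severe).
#'
#' @param core_mask,penumbra_mask logical arrays of the same shape
#' @return nonnegative ratio (possibly Inf)
#' @export
mismatch_ratio <- function(core_mask, penumbra_mask) {
  if (!identical(dim(core_mask), dim(penumbra_mask))) {
    stop("mask shape mismatch")
  }
  nc <- sum(core_mask); np <- sum(penumbra_mask)
  if (np == 0) {
    if (nc == 0) 0 else Inf
  } else {
    nc / np
  }
}

#' Classify ischemia severity from the mismatch ratio
#'
#' `none` at ratio 0; `mild_moderate` for ratios in (0, 0.5];
#' `severe` above 0.5.
#'
#' @param ratio nonnegative mismatch ratio (Inf allowed)
#' @return factor with levels none, mild_moderate, severe
#' @export
classify_severity <- function(ratio) {
  if (is.na(ratio) || ratio < 0) stop("ratio must be nonnegative")
  lab <- if (ratio == 0) "none" else if (ratio <= 0.5) "mild_moderate"
         else "severe"
  factor(lab, levels = c("none", "mild_moderate", "severe"))
}

#' Derive core/penumbra masks from perfusion maps
#'
#' Operationalizes the relative thresholds used for real data: core where
#' CBF falls below 30% of the mirrored contralateral median (within the
#' brain), penumbra where TTP exceeds the contralateral median by more
#' than 6 s.
#'
#' @param cbf,ttp physical-unit slices or volumes
#' @param brain_mask logical mask of the same shape
#' @return list with `core_mask` and `penumbra_mask`
#' @export
derive_ischemia_masks <- function(cbf, ttp, brain_mask) {
  d <- dim(cbf)
  mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  one_slice <- function(cb, tp, bm) {
    core <- pen <- matrix(FALSE, nrow(cb), ncol(cb))
    if (!any(bm)) return(list(core = core, pen = pen))
    cbm <- mirror(cb); tpm <- mirror(tp); bmm <- mirror(bm)
    both <- bm & bmm
    core[both] <- cb[both] < 0.3 * cbm[both]
    pen[both] <- tp[both] > tpm[both] + 6
    list(core = core, pen = pen | core)
  }
  if (length(d) == 2) {
    r <- one_slice(cbf, ttp, brain_mask)
    return(list(core_mask = r$core, penumbra_mask = r$pen))
  }
  core <- pen <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    r <- one_slice(cbf[, , z], ttp[, , z], brain_mask[, , z])
    core[, , z] <- r$core; pen[, , z] <- r$pen
  }
  list(core_mask = core, penumbra_mask = pen)
}

#' Evaluate predicted perfusion maps against reference cases
#'
#' Pairs predictions with references by case id, computes per-case,
#' per-map SSIM and UQI on normalized maps cropped to the reference brain
#' bounding box (averaged over slices), and attaches the reference
#' mismatch ratio and severity class.
#'
#' @param predicted named list (by case id); each element a named list of
#'   the four maps in physical units, (H, W) or (H, W, Z)
#' @param reference list of `ctpgan_phantom` cases (or named list of
#'   case-like lists with maps, `brain_mask`, `core_mask`,
#'   `penumbra_mask`, `case_id`)
#' @param ssim_args,uqi_args optional argument lists for [ssim()]/[uqi()]
#' @return data.frame with columns case_id, map_kind, ssim, uqi, ratio,
#'   severity
#' @export
evaluate_cohort <- function(predicted, reference,
                            ssim_args = list(), uqi_args = list()) {
  ref_ids <- vapply(reference, function(x) x$case_id, character(1))
  names(reference) <- ref_ids
  if (is.null(names(predicted)) || !setequal(names(predicted), ref_ids)) {
    stop("predictions and references must pair one-to-one by case id")
  }
  rows <- list()
  for (id in ref_ids) {
    ref <- reference[[id]]
    ratio <- mismatch_ratio(ref$core_mask, ref$penumbra_mask)
    sev <- classify_severity(ratio)
    for (kind in MAP_KINDS) {
      pv <- predicted[[id]][[kind]]
      rv <- ref[[kind]]
      if (is.null(pv)) stop("case ", id, " missing predicted ", kind)
      if (length(dim(pv)) == 2) pv <- array(pv, dim = c(dim(pv), 1))
      ss <- uu <- numeric(0)
      for (z in seq_len(dim(pv)[3])) {
        rz <- if (length(dim(rv)) == 3) {
          zi <- if (!is.null(attr(pv, "positions")))
            attr(pv, "positions")[z] else z
          rv[, , zi]
        } else rv
        bmz <- if (length(dim(ref$brain_mask)) == 3) {
          zi <- if (!is.null(attr(pv, "positions")))
            attr(pv, "positions")[z] else z
          ref$brain_mask[, , zi]
        } else ref$brain_mask
        box <- brain_bounding_box(bmz)
        a <- crop_to_box(normalize_map(pv[, , z], kind), box)
        b <- crop_to_box(normalize_map(rz, kind), box)
        ss <- c(ss, do.call(ssim, c(list(a, b), ssim_args)))
        uu <- c(uu, do.call(uqi, c(list(a, b), uqi_args)))
      }
      rows[[length(rows) + 1]] <- data.frame(
        case_id = id, map_kind = kind, ssim = mean(ss), uqi = mean(uu),
        ratio = ratio, severity = as.character(sev))
    }
  }
  do.call(rbind, rows)
}

#' Convert an [infer_volume()] result to [evaluate_cohort()] input
#'
#' Attaches the predicted axial positions to each map so the evaluator
#' compares against the matching reference slices.
#'
#' @param vols output of [infer_volume()]
#' @return named list of the four maps with a `positions` attribute
#' @export
as_predicted <- function(vols) {
  lapply(vols[c("cbf", "cbv", "mtt", "ttp")], function(v) {
    attr(v, "positions") <- vols$positions
    v
  })
}

#' Stratified summary of an evaluation report
#'
#' Means and quartiles of SSIM/UQI by severity class and by the binary
#' (ratio = 0 vs ratio > 0) stratification.
#'
#' @param report output of [evaluate_cohort()]
#' @return data.frame of stratified summaries
#' @export
summarize_eval <- function(report) {
  strat <- function(key, label) {
    groups <- split(report, list(report$map_kind, key), drop = TRUE)
    out <- lapply(names(groups), function(g) {
      d <- groups[[g]]
      data.frame(stratum_by = label,
                 stratum = sub("^[^.]*\\.", "", g),
                 map_kind = d$map_kind[1],
                 n = nrow(d),
                 ssim_mean = mean(d$ssim),
                 ssim_q1 = unname(stats::quantile(d$ssim, 0.25)),
                 ssim_q3 = unname(stats::quantile(d$ssim, 0.75)),
                 uqi_mean = mean(d$uqi),
                 uqi_q1 = unname(stats::quantile(d$uqi, 0.25)),
                 uqi_q3 = unname(stats::quantile(d$uqi, 0.75)))
    })
    do.call(rbind, out)
  }
  rbind(strat(report$severity, "severity"),
        strat(ifelse(report$ratio > 0, "ratio>0", "ratio=0"), "ratio"))
}
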