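# Preprocessing: HU windowing, perfusion-map normalization, pseudo-RGB
# slice stacking, threshold-morphology skull stripping, bilinear resize,
# and paired static augmentation.
#
# Order of operations: window -> skull-strip -> resize -> pseudo-RGB stack
# -> map normalization -> static augmentation; z-scoring with training-pool
# statistics happens only at the network input boundary.

#' Hounsfield display window
#'
#' @param center window center, HU (brain window default 40)
#' @param width window width, HU (default 80; must be positive)
#' @return a `ctpgan_window` list
#' @export
window_spec <- function(center = 40, width = 80) {
  if (width <= 0) stop("window width must be positive")
  structure(list(center = center, width = width), class = "ctpgan_window")
}

#' Window a HU image or volume to [0, 1]
#'
#' Linear map of `[center - width/2, center + width/2]` to [0, 1], clipped
#' outside.
#'
#' @param volume HU array (any shape, finite values)
#' @param w a [window_spec()]
#' @return array of the same shape in [0, 1]
#' @export
window_hu <- function(volume, w = window_spec()) {
  if (any(!is.finite(volume))) stop("non-finite HU values")
  lo <- w$center - w$width / 2
  pmin(pmax((volume - lo) / w$width, 0), 1)
}

#' Normalize a perfusion map to [0, 1] by its canonical physiological range
#'
#' @param map physical-unit array
#' @param kind one of "cbf", "cbv", "mtt", "ttp"
#' @return array in [0, 1] (clipped)
#' @export
normalize_map <- function(map, kind) {
  r <- map_ranges()[[match.arg(kind, names(map_ranges()))]]
  pmin(pmax((map - r[1]) / (r[2] - r[1]), 0), 1)
}

#' Invert [normalize_map()]
#'
#' @param map normalized array in [0, 1]
#' @param kind map kind
#' @return physical-unit array
#' @export
denormalize_map <- function(map, kind) {
  r <- map_ranges()[[match.arg(kind, names(map_ranges()))]]
  r[1] + map * (r[2] - r[1])
}

#' Admissible axial positions for pseudo-RGB stacking
#'
#' Positions with both +/- offset neighbors inside the volume: the
#' boundary `round(offset_mm / spacing)` slices on each side are excluded,
#' so a volume of Z slices admits `Z - 2 * round(offset_mm / spacing)`
#' positions.
#'
#' @param n_slices axial slice count
#' @param offset_mm pseudo-RGB vertical offset in mm
#' @param spacing axial spacing in mm
#' @return integer vector of admissible slice indices (1-based)
#' @export
admissible_positions <- function(n_slices, offset_mm = 4, spacing = 1) {
  o <- round(offset_mm / spacing)
  z <- seq_len(n_slices)
  z[z - o >= 1 & z + o <= n_slices]
}

#' Stack three NCCT slices into a pseudo-RGB image
#'
#' Channels are ordered (slice below, center slice, slice above) at a
#' vertical offset of `offset_mm`, rounded to the nearest whole slice.
#'
#' @param ncct HU volume, dim (H, W, Z)
#' @param z center slice index (1-based)
#' @param offset_mm vertical offset in mm (default 4)
#' @param spacing axial slice spacing in mm
#' @return array (H, W, 3)
#' @export
stack_pseudo_rgb <- function(ncct, z, offset_mm = 4, spacing = 1) {
  o <- round(offset_mm / spacing)
  Z <- dim(ncct)[3]
  if (z - o < 1 || z + o > Z) {
    stop("slice ", z, " with offset ", o,
         " slices falls outside the volume (1..", Z, ")")
  }
  out <- array(0, dim = c(dim(ncct)[1:2], 3))
  out[, , 1] <- ncct[, , z - o]
  out[, , 2] <- ncct[, , z]
  out[, , 3] <- ncct[, , z + o]
  out
}

#' Threshold-morphology skull stripping of a windowed slice
#'
#' Keeps pixels strictly inside the display window (saturated bone and
#' background are excluded), takes the largest 4-connected component and
#' fills its interior holes.
#'
#' @param slice windowed image in [0, 1]
#' @param lo,hi exclusive thresholds defining "inside the window"
#' @return logical brain mask
#' @export
skull_strip <- function(slice, lo = 0.02, hi = 0.98) {
  cand <- slice > lo & slice < hi
  if (!any(cand)) stop("empty brain mask: no sub-skull tissue found")
  lab <- .label_components(cand)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  # fill holes: background components of the complement not touching the
  # image border are interior to the mask
  comp <- .label_components(!mask)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  hole <- !mask & !(comp %in% setdiff(border, 0L))
  mask | matrix(hole, nrow(mask), ncol(mask))
}

interp_weights_1d <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  f <- floor(src)
  w <- src - f
  i0 <- pmin(pmax(f, 1), n_in)
  i1 <- pmin(pmax(f + 1, 1), n_in)
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), i0)] <- A[cbind(seq_len(n_out), i0)] + (1 - w)
  A[cbind(seq_len(n_out), i1)] <- A[cbind(seq_len(n_out), i1)] + w
  A
}

#' Resize an image (bilinear) or mask (nearest neighbor)
#'
#' Pixel-center-aligned sampling; idempotent when the input is already at
#' the target size.
#'
#' @param img matrix, or (H, W, C) array (resized per channel)
#' @param size target side length
#' @param method "bilinear" for intensities, "nearest" for masks
#' @return resized image
#' @export
resize_to <- function(img, size = 256, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(img)
  if (length(d) == 3) {
    out <- array(0, dim = c(size, size, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_to(img[, , c], size, method)
    return(out)
  }
  if (method == "bilinear") {
    R <- interp_weights_1d(d[1], size)
    C <- interp_weights_1d(d[2], size)
    R %*% img %*% t(C)
  } else {
    # nearest: round the center-aligned source coordinate
    src_r <- (seq_len(size) - 0.5) * d[1] / size + 0.5
    src_c <- (seq_len(size) - 0.5) * d[2] / size + 0.5
    ri <- pmin(pmax(floor(src_r + 0.5), 1), d[1])
    ci <- pmin(pmax(floor(src_c + 0.5), 1), d[2])
    img[ri, ci]
  }
}

#' Augmentation specification
#'
#' @param p_hflip probability of a horizontal reflection
#' @param rotation_range rotations are uniform in +/- this many degrees
#' @param translation_range translations are uniform integers in +/- this
#'   many pixels, per axis
#' @param copies_per_slice augmented variants emitted per source slice by
#'   [build_training_set()]
#' @return a `ctpgan_augment` list
#' @export
aug_spec <- function(p_hflip = 0.5, rotation_range = 10,
                     translation_range = 30, copies_per_slice = 1) {
  structure(list(p_hflip = p_hflip, rotation_range = rotation_range,
                 translation_range = translation_range,
                 copies_per_slice = as.integer(copies_per_slice)),
            class = "ctpgan_augment")
}

# Resample an image under (flip -> rotate about center -> integer
# translate), inverse-mapping each output pixel; out-of-frame regions fill
# with 0. Bilinear for intensities, nearest for masks.
apply_transform <- function(img, flip = FALSE, theta = 0, tx = 0, ty = 0,
                            method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  rc <- (H + 1) / 2; cc <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  yr <- g$r - ty - rc
  xc <- g$c - tx - cc
  th <- theta * pi / 180
  xs <- cos(th) * xc + sin(th) * yr + cc
  ys <- -sin(th) * xc + cos(th) * yr + rc
  if (flip) xs <- W + 1 - xs
  was_logical <- is.logical(img)
  if (was_logical) img <- img * 1
  if (method == "nearest") {
    ri <- floor(ys + 0.5); ci <- floor(xs + 0.5)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- numeric(H * W)
    v[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(ys); c0 <- floor(xs)
    wr <- ys - r0; wc <- xs - c0
    v <- numeric(H * W)
    for (dr in 0:1) {
      for (dc in 0:1) {
        ri <- r0 + dr; ci <- c0 + dc
        wt <- (if (dr) wr else 1 - wr) * (if (dc) wc else 1 - wc)
        ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W & wt > 0
        v[ok] <- v[ok] + wt[ok] * img[cbind(ri[ok], ci[ok])]
      }
    }
  }
  out <- matrix(v, H, W)
  if (was_logical) out >= 0.5 else out
}

draw_transform <- function(a) {
  list(flip = stats::runif(1) < a$p_hflip,
       theta = stats::runif(1, -a$rotation_range, a$rotation_range),
       tx = sample(seq(-a$translation_range, a$translation_range), 1),
       ty = sample(seq(-a$translation_range, a$translation_range), 1))
}

#' Augment a paired slice
#'
#' Draws one (flip, rotation, translation) transform from the current RNG
#' and applies it identically to all NCCT channels, all perfusion maps and
#' the brain mask (bilinear / nearest respectively; fill 0).
#'
#' @param s a paired slice (see [paired_slices_from_phantom()])
#' @param a an [aug_spec()]
#' @param transform optional fixed transform list (flip, theta, tx, ty)
#'   instead of a random draw
#' @return the transformed paired slice (transform recorded in
#'   `$transform`)
#' @export
augment <- function(s, a = aug_spec(), transform = NULL) {
  tr <- if (is.null(transform)) draw_transform(a) else transform
  for (ch in 1:3) {
    s$ncct3[, , ch] <- apply_transform(s$ncct3[, , ch], tr$flip, tr$theta,
                                       tr$tx, tr$ty, "bilinear")
  }
  s$maps <- lapply(s$maps, apply_transform, flip = tr$flip,
                   theta = tr$theta, tx = tr$tx, ty = tr$ty,
                   method = "bilinear")
  s$brain_mask <- apply_transform(s$brain_mask, tr$flip, tr$theta,
                                  tr$tx, tr$ty, "nearest")
  s$transform <- tr
  s
}

#' Extract paired training slices from a phantom case
#'
#' For each admissible axial position (those with both +/- offset
#' neighbors), windows the NCCT slice triplet, skull-strips on the center
#' slice, resizes, normalizes the four perfusion maps, and applies the
#' brain mask multiplicatively.
#'
#' @param case a `ctpgan_phantom`
#' @param window a [window_spec()]
#' @param offset_mm pseudo-RGB vertical offset in mm
#' @param size output side length (default: the phantom's own size)
#' @return list of paired slices, each a list with `ncct3` (H, W, 3 in
#'   [0,1]), `maps` (named list of 4 normalized H x W matrices),
#'   `brain_mask`, `z_index`, `case_id`
#' @export
paired_slices_from_phantom <- function(case, window = window_spec(),
                                       offset_mm = 4, size = NULL) {
  if (is.null(size)) size <- dim(case$ncct)[1]
  zs <- admissible_positions(dim(case$ncct)[3], offset_mm, case$spacing)
  if (!length(zs)) stop("volume too thin for the pseudo-RGB offset")
  win <- window_hu(case$ncct, window)
  lapply(zs, function(z) {
    ncct3 <- stack_pseudo_rgb(win, z, offset_mm, case$spacing)
    mask <- skull_strip(ncct3[, , 2])
    ncct3 <- resize_to(ncct3, size, "bilinear")
    mask <- resize_to(mask, size, "nearest")
    for (ch in 1:3) ncct3[, , ch] <- ncct3[, , ch] * mask
    maps <- lapply(stats::setNames(MAP_KINDS, MAP_KINDS), function(k) {
      m <- resize_to(case[[k]][, , z], size, "bilinear")
      normalize_map(m, k) * mask
    })
    list(ncct3 = ncct3, maps = maps, brain_mask = mask, z_index = z,
         case_id = case$case_id)
  })
}

#' Build a static augmented training set
#'
#' Emits `copies_per_slice` augmented variants per source slice with
#' reproducible per-item seeds, and records the global NCCT mean/sd used
#' for z-score standardization at the network input boundary.
#'
#' @param cases list of `ctpgan_phantom`
#' @param a an [aug_spec()]
#' @param seed master seed
#' @param window,offset_mm,size forwarded to
#'   [paired_slices_from_phantom()]
#' @return list with `samples` (paired slices) and `stats`
#'   (`mean`, `sd` of the pooled NCCT channels)
#' @export
build_training_set <- function(cases, a = aug_spec(), seed = 1,
                               window = window_spec(), offset_mm = 4,
                               size = NULL) {
  if (!length(cases)) stop("empty case list")
  src <- unlist(lapply(cases, paired_slices_from_phantom, window = window,
                       offset_mm = offset_mm, size = size),
                recursive = FALSE)
  n_items <- length(src) * a$copies_per_slice
  item_seeds <- with_seed(seed, sample.int(2^31 - 2, n_items))
  samples <- vector("list", n_items)
  k <- 0
  for (s in src) {
    for (cp in seq_len(a$copies_per_slice)) {
      k <- k + 1
      samples[[k]] <- with_seed(item_seeds[k], augment(s, a))
    }
  }
  pool <- unlist(lapply(samples, function(s) as.numeric(s$ncct3)))
  list(samples = samples,
       stats = list(mean = mean(pool), sd = stats::sd(pool)))
}

#' Z-score an NCCT tensor with training-pool statistics
#'
#' @param x array
#' @param stats list with `mean` and `sd`
#' @return standardized array
#' @export
standardize_ncct <- function(x, stats) {
  (x - stats$mean) / stats$sd
}
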