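# The four-term training objective: adversarial (PatchGAN), L1, extrema
# and multimodal (central volume principle) losses, with their analytic
# gradients with respect to the generated maps. All losses operate in
# normalized [0,1] map space. Min-max statistics for the extrema loss are
# computed per slice, within the brain mask when one is supplied.

#' Loss weights
#'
#' @param lambda1 weight of the L1 fidelity term
#' @param lambda2 weight of the extrema term
#' @param lambda3 weight of the multimodal (central-volume) term
#' @param eps guard for min-max normalization and log terms
#' @param non_saturating if TRUE (default) the generator minimizes
#'   `-log D(fake)` rather than `log(1 - D(fake))`
#' @param mml_scale optional consistency factor multiplying the CBF*MTT
#'   product in the multimodal loss (1 = the literal normalized product;
#'   3 would make the product dimensionally consistent with normalized CBV
#'   given the canonical normalization ranges)
#' @return a `ctpgan_loss_weights` list
#' @export
loss_weights <- function(lambda1 = 100, lambda2 = 100, lambda3 = 10,
                         eps = 1e-7, non_saturating = TRUE, mml_scale = 1) {
  if (lambda1 < 0 || lambda2 < 0 || lambda3 < 0) {
    stop("loss weights must be nonnegative")
  }
  if (eps <= 0) stop("eps must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 eps = eps, non_saturating = non_saturating,
                 mml_scale = mml_scale),
            class = "ctpgan_loss_weights")
}

clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Adversarial (GAN) loss from patch probability maps
#'
#' Discriminator loss is `-[mean log d_real + mean log(1 - d_fake)]`;
#' generator loss is the non-saturating `-mean log d_fake` (or the
#' saturating `mean log(1 - d_fake)` when requested). When lists are given,
#' losses are averaged over the map kinds (the 1/N prefactor of the
#' objective).
#'
#' @param d_real,d_fake patch probability arrays in (0,1), or lists of them
#'   (one per map kind)
#' @param eps clamp guard for probabilities at exactly 0/1
#' @param non_saturating generator-loss form
#' @return list with `loss_D` and `loss_G`
#' @export
gan_loss <- function(d_real, d_fake, eps = 1e-7, non_saturating = TRUE) {
  if (!is.list(d_real)) d_real <- list(d_real)
  if (!is.list(d_fake)) d_fake <- list(d_fake)
  stopifnot(length(d_real) == length(d_fake))
  ld <- lg <- 0
  for (i in seq_along(d_real)) {
    dr <- clamp01(d_real[[i]], eps)
    df <- clamp01(d_fake[[i]], eps)
    ld <- ld - mean(log(dr)) - mean(log(1 - df))
    lg <- lg + if (non_saturating) -mean(log(df)) else mean(log(1 - df))
  }
  list(loss_D = ld / length(d_real), loss_G = lg / length(d_real))
}

#' L1 fidelity loss
#'
#' Mean absolute difference, averaged over pixels and then over the map
#' kinds when lists are given.
#'
#' @param generated,real arrays in [0,1] map space, or lists of them
#' @return scalar
#' @export
l1_loss <- function(generated, real) {
  if (!is.list(generated)) generated <- list(generated)
  if (!is.list(real)) real <- list(real)
  stopifnot(length(generated) == length(real))
  v <- 0
  for (i in seq_along(generated)) {
    if (!identical(dim(generated[[i]]), dim(real[[i]]))) {
      stop("shape mismatch between generated and real maps")
    }
    v <- v + mean(abs(generated[[i]] - real[[i]]))
  }
  v / length(generated)
}

l1_grad <- function(generated, real) {
  sign(generated - real) / length(generated)
}

#' Multimodal (central volume principle) loss
#'
#' Mean absolute difference between the elementwise product of the
#' synthesized CBF and MTT maps and the real CBV map, all in normalized
#' [0,1] space (the product is taken literally on normalized values).
#'
#' @param gen_cbf,gen_mtt synthesized CBF and MTT maps (same shape)
#' @param real_cbv real CBV map
#' @param mask optional logical mask restricting the average
#' @param scale optional consistency factor on the product (default 1)
#' @return scalar
#' @export
multimodal_loss <- function(gen_cbf, gen_mtt, real_cbv, mask = NULL,
                            scale = 1) {
  if (!identical(dim(gen_cbf), dim(gen_mtt)) ||
      !identical(dim(gen_cbf), dim(real_cbv))) {
    stop("shape mismatch between CBF, MTT and CBV maps")
  }
  r <- abs(scale * gen_cbf * gen_mtt - real_cbv)
  if (is.null(mask)) mean(r) else mean(r[mask])
}

multimodal_grad <- function(gen_cbf, gen_mtt, real_cbv, mask = NULL,
                            scale = 1) {
  s <- sign(scale * gen_cbf * gen_mtt - real_cbv)
  if (is.null(mask)) {
    s <- s / length(s)
  } else {
    s[!mask] <- 0
    s <- s / sum(mask)
  }
  list(d_cbf = s * scale * gen_mtt, d_mtt = s * scale * gen_cbf)
}

minmax01 <- function(x, idx = NULL, eps = 1e-12) {
  v <- if (is.null(idx)) x else x[idx]
  rng <- range(v)
  if (diff(rng) < eps) return(NULL)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Extrema weight map
#'
#' `W = ((PM - min) / (max - min) - 0.5)^2`: pixels far from the slice
#' midrange (very high or very low perfusion, i.e. candidate ischemic
#' tissue) receive weights up to 0.25.
#'
#' @param pm a real perfusion map (matrix or array, one slice)
#' @param mask optional logical mask; min-max statistics and weights are
#'   computed within it
#' @param eps degeneracy guard
#' @return weight array (0 outside the mask); a constant map yields an
#'   all-zero weight map with a warning
#' @export
extrema_weight_map <- function(pm, mask = NULL, eps = 1e-12) {
  idx <- if (is.null(mask)) NULL else which(mask)
  u <- minmax01(pm, idx, eps)
  if (is.null(u)) {
    warning("constant perfusion map: extrema weight map is zero")
    w <- pm * 0
  } else {
    w <- (u - 0.5)^2
  }
  if (!is.null(mask)) w[!mask] <- 0
  w
}

#' Extrema loss for one slice pair
#'
#' Min-max normalizes the generated and the real map (per slice, within
#' the mask), takes the squared difference, weights it by
#' [extrema_weight_map()] of the real map, and averages. With lists, the
#' result is additionally averaged over map kinds.
#'
#' @param generated,real maps or lists of maps
#' @param mask optional logical mask (or list of masks)
#' @param eps degeneracy guard; a constant generated map contributes via a
#'   zero normalized image
#' @return scalar
#' @export
extrema_loss <- function(generated, real, mask = NULL, eps = 1e-12) {
  if (!is.list(generated)) {
    generated <- list(generated); real <- list(real)
    if (!is.null(mask)) mask <- list(mask)
  }
  v <- 0
  for (i in seq_along(generated)) {
    g <- generated[[i]]; r <- real[[i]]
    if (!identical(dim(g), dim(r))) stop("shape mismatch")
    mk <- if (is.null(mask)) NULL else mask[[i]]
    idx <- if (is.null(mk)) NULL else which(mk)
    w <- suppressWarnings(extrema_weight_map(r, mk, eps))
    ug <- minmax01(g, idx, eps)
    ur <- minmax01(r, idx, eps)
    if (is.null(ug)) ug <- g * 0
    if (is.null(ur)) ur <- r * 0
    h <- (ug - ur)^2
    v <- v + if (is.null(idx)) mean(w * h) else mean((w * h)[idx])
  }
  v / length(generated)
}

# Gradient of the extrema loss with respect to the generated map,
# including the dependence of the min/max statistics on the pixels that
# attain them (first index on ties).
extrema_grad <- function(generated, real, mask = NULL, eps = 1e-12) {
  idx <- if (is.null(mask)) seq_along(generated) else which(mask)
  P <- length(idx)
  w <- suppressWarnings(extrema_weight_map(real, mask, eps))
  ur <- minmax01(real, if (is.null(mask)) NULL else idx, eps)
  if (is.null(ur)) ur <- real * 0
  gv <- generated[idx]
  rng <- range(gv)
  out <- generated * 0
  if (diff(rng) < eps) return(out)
  ug <- (generated - rng[1]) / (rng[2] - rng[1])
  s <- 2 * w * (ug - ur) / P          # dL/du, elementwise
  s_idx <- s[idx]
  u_idx <- ug[idx]
  amin <- idx[which.min(gv)]
  amax <- idx[which.max(gv)]
  out[idx] <- s_idx / diff(rng)
  out[amin] <- out[amin] + sum(s_idx * (u_idx - 1)) / diff(rng)
  out[amax] <- out[amax] + sum(s_idx * (-u_idx)) / diff(rng)
  out
}

#' Combine loss components into the training objective
#'
#' `total_G = gan_G + lambda1 * l1 + lambda2 * extrema +
#' lambda3 * multimodal`; `total_D = gan_D`.
#'
#' @param components list with elements `gan_G`, `gan_D`, `l1`, `extrema`,
#'   `multimodal` (scalars computed on the same batch)
#' @param weights a [loss_weights()]
#' @return a `ctpgan_loss_report` list with the components and totals
#' @export
total_objective <- function(components, weights = loss_weights()) {
  stopifnot(inherits(weights, "ctpgan_loss_weights"))
  need <- c("gan_G", "gan_D", "l1", "extrema", "multimodal")
  missing <- setdiff(need, names(components))
  if (length(missing)) stop("missing components: ",
                            paste(missing, collapse = ", "))
  rep <- components[need]
  rep$total_G <- rep$gan_G + weights$lambda1 * rep$l1 +
    weights$lambda2 * rep$extrema + weights$lambda3 * rep$multimodal
  rep$total_D <- rep$gan_D
  class(rep) <- "ctpgan_loss_report"
  rep
}
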