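# Multitask generator and PatchGAN discriminators.
#
# The generator is a shared-encoder U-Net: the first `shared_depth` encoder
# stages are common to all four perfusion-map branches; each branch then has
# its own remaining encoder stages (down to a 1x1 bottleneck), a full
# skip-connected decoder, and a PILO (physician-in-the-loop) output layer.
# The PILO layer is a 1x1 transposed convolution over the 4-channel
# concatenation of the branch output (rescaled from tanh [-1,1] to [0,1] map
# space) and the 3-channel pseudo-RGB NCCT input; its input-channel weight
# slices can be rescaled at inference to trade hemodynamic against
# anatomical content.
#
# Parameter ledger (fixed by reconciling block-level counts against the
# published totals): every convolution and transposed convolution carries a
# bias; normalization layers carry no learnable affine parameters. Under
# this ledger the default 256x256 configuration has exactly 209,352,408
# trainable generator parameters and 11,063,044 across the four
# discriminators.

MAP_KINDS <- c("cbf", "cbv", "mtt", "ttp")

#' Network architecture configuration
#'
#' @param image_size input side length in pixels (power of two; the encoder
#'   halves it down to a 1x1 bottleneck, so the number of encoder stages is
#'   `log2(image_size)`)
#' @param input_channels NCCT input channels (3: pseudo-RGB slice triplet)
#' @param map_count number of perfusion-map branches
#' @param base_width channels of the first encoder stage; deeper stages use
#'   the ladder `base_width * min(2^(stage-1), 8)`
#' @param shared_depth number of encoder stages shared across branches
#' @param kernel,stride,padding convolution geometry of every stage
#' @param leaky_slope negative slope of the LeakyReLU activations
#' @param norm_kind "auto" selects batch normalization when the batch has
#'   more than one sample and instance normalization otherwise; "batch" or
#'   "instance" force a kind
#' @param pilo_kernel kernel size of the PILO output layer
#' @param init_sd standard deviation of the zero-mean Gaussian weight
#'   initialization
#' @return a `ctpgan_config` list
#' @export
network_config <- function(image_size = 256, input_channels = 3,
                           map_count = 4, base_width = 64, shared_depth = 4,
                           kernel = 4, stride = 2, padding = 1,
                           leaky_slope = 0.2,
                           norm_kind = c("auto", "batch", "instance"),
                           pilo_kernel = 1, init_sd = 0.02) {
  norm_kind <- match.arg(norm_kind)
  stages <- log2(image_size)
  if (stages != round(stages) || stages < 3) {
    stop("image_size must be a power of two, at least 8")
  }
  stages <- as.integer(stages)
  if (shared_depth >= stages) {
    shared_depth <- stages - 1L
  }
  widths <- base_width * pmin(2^(seq_len(stages) - 1), 8)
  cfg <- list(image_size = as.integer(image_size),
              input_channels = as.integer(input_channels),
              map_count = as.integer(map_count),
              map_kinds = MAP_KINDS[seq_len(map_count)],
              base_width = as.integer(base_width),
              stages = stages,
              shared_depth = as.integer(shared_depth),
              encoder_widths = as.integer(widths),
              kernel = as.integer(kernel), stride = as.integer(stride),
              padding = as.integer(padding),
              leaky_slope = leaky_slope, norm_kind = norm_kind,
              pilo_kernel = as.integer(pilo_kernel), init_sd = init_sd)
  class(cfg) <- "ctpgan_config"
  cfg
}

resolve_norm_kind <- function(cfg, n_batch) {
  if (cfg$norm_kind != "auto") return(cfg$norm_kind)
  if (n_batch > 1) "batch" else "instance"
}

# decoder ladder: stage j outputs the width of encoder stage (S - j), the
# last stage outputs one channel; inputs after stage 1 are doubled by the
# skip concatenation
decoder_widths <- function(widths) {
  S <- length(widths)
  out <- c(rev(widths)[-1], 1L)
  inp <- c(widths[S], out[-S] + rev(widths)[2:S])
  list(input = as.integer(inp), output = as.integer(out))
}

#' Build the multitask generator
#'
#' @param cfg a [network_config()]
#' @param seed integer seed for the Gaussian weight initialization; two
#'   builds with the same seed are identical
#' @return a `ctpgan_generator` handle
#' @export
build_generator <- function(cfg = network_config(), seed = 1) {
  S <- cfg$stages
  w <- cfg$encoder_widths
  dw <- decoder_widths(w)
  k <- cfg$kernel
  with_seed(seed, {
    enc_layer <- function(s) {
      cin <- if (s == 1) cfg$input_channels else w[s - 1]
      new_layer("conv", k, cin, w[s], cfg$stride, cfg$padding,
                norm = (s > 1 && s < S), act = "lrelu",
                init_sd = cfg$init_sd)
    }
    shared <- lapply(seq_len(cfg$shared_depth), enc_layer)
    branches <- list()
    for (kind in cfg$map_kinds) {
      enc <- lapply((cfg$shared_depth + 1):S, enc_layer)
      dec <- lapply(seq_len(S), function(j) {
        new_layer("tconv", k, dw$input[j], dw$output[j],
                  cfg$stride, cfg$padding,
                  norm = (j < S), act = if (j == S) "tanh" else "lrelu",
                  init_sd = cfg$init_sd)
      })
      pilo <- new_layer("tconv", cfg$pilo_kernel, cfg$input_channels + 1, 1,
                        stride = 1, pad = 0, norm = FALSE, act = "none",
                        init_sd = cfg$init_sd)
      branches[[kind]] <- list(enc = enc, dec = dec, pilo = pilo)
    }
    structure(list(cfg = cfg, seed = seed, shared = shared,
                   branches = branches),
              class = "ctpgan_generator")
  })
}

#' Build one PatchGAN discriminator
#'
#' Five convolution stages (strides 2,2,2,1,1; widths
#' `base_width * (1,2,4,8)` then 1) over the 4-channel concatenation of the
#' pseudo-RGB NCCT and one perfusion map, ending in a sigmoid patch
#' probability map with a theoretical 70x70 receptive field at the default
#' geometry.
#'
#' @inheritParams build_generator
#' @return a `ctpgan_discriminator` handle
#' @export
build_discriminator <- function(cfg = network_config(), seed = 1) {
  k <- cfg$kernel
  widths <- c(cfg$base_width * c(1, 2, 4, 8), 1)
  strides <- c(2, 2, 2, 1, 1)
  cin <- c(cfg$input_channels + 1, widths[-5])
  with_seed(seed, {
    layers <- lapply(1:5, function(i) {
      new_layer("conv", k, cin[i], widths[i], strides[i], cfg$padding,
                norm = (i %in% 2:4),
                act = if (i == 5) "sigmoid" else "lrelu",
                init_sd = cfg$init_sd)
    })
    structure(list(cfg = cfg, seed = seed, layers = layers),
              class = "ctpgan_discriminator")
  })
}

#' Build the four map-specific discriminators
#'
#' @inheritParams build_generator
#' @return named list of `ctpgan_discriminator`, one per map kind
#' @export
build_discriminators <- function(cfg = network_config(), seed = 1) {
  ds <- lapply(seq_along(cfg$map_kinds), function(i) {
    build_discriminator(cfg, seed = seed + i - 1)
  })
  names(ds) <- cfg$map_kinds
  ds
}

# ---- forward / backward -----------------------------------------------

#' Generator forward pass
#'
#' @param gen a `ctpgan_generator`
#' @param x input tensor, dim (H, W, input_channels, N)
#' @param keep_cache retain intermediate activations for a backward pass
#' @param norm_kind override the normalization kind ("batch"/"instance")
#' @return list with `maps` (named list of (H, W, 1, N) tensors in [0,1]
#'   map space) and, if requested, `cache`
#' @export
gen_forward <- function(gen, x, keep_cache = FALSE, norm_kind = NULL) {
  cfg <- gen$cfg
  d <- tensor_dim(x)
  if (d[1] != cfg$image_size || d[3] != cfg$input_channels) {
    stop("input tensor does not match the configured image size / channels")
  }
  nk <- if (is.null(norm_kind)) resolve_norm_kind(cfg, d[4]) else norm_kind
  S <- cfg$stages
  sd_ <- cfg$shared_depth
  sl <- cfg$leaky_slope

  shared_acts <- vector("list", sd_)
  shared_caches <- vector("list", sd_)
  h <- x
  for (i in seq_len(sd_)) {
    lf <- layer_fwd(gen$shared[[i]], h, nk, sl)
    shared_acts[[i]] <- h <- lf$y
    shared_caches[[i]] <- lf$cache
  }

  maps <- list()
  bcache <- list()
  for (kind in cfg$map_kinds) {
    br <- gen$branches[[kind]]
    acts <- vector("list", S)
    ecache <- vector("list", S - sd_)
    for (i in seq_len(sd_)) acts[[i]] <- shared_acts[[i]]
    hb <- shared_acts[[sd_]]
    for (j in seq_len(S - sd_)) {
      lf <- layer_fwd(br$enc[[j]], hb, nk, sl)
      acts[[sd_ + j]] <- hb <- lf$y
      ecache[[j]] <- lf$cache
    }
    dcache <- vector("list", S)
    hd <- acts[[S]]
    for (j in seq_len(S)) {
      inp <- if (j == 1) hd else concat_channels(hd, acts[[S - j + 1]])
      lf <- layer_fwd(br$dec[[j]], inp, nk, sl)
      hd <- lf$y
      dcache[[j]] <- lf$cache
    }
    y01 <- (hd + 1) / 2
    pin <- concat_channels(y01, x)
    pf <- layer_fwd(br$pilo, pin, nk, sl)
    maps[[kind]] <- pf$y
    if (keep_cache) {
      bcache[[kind]] <- list(enc = ecache, dec = dcache, pilo = pf$cache,
                             acts = if (keep_cache) acts else NULL)
    }
  }
  out <- list(maps = maps)
  if (keep_cache) {
    out$cache <- list(norm_kind = nk, x = x, shared_acts = shared_acts,
                      shared_caches = shared_caches, branches = bcache)
  }
  out
}

# Backward pass through the generator. dmaps: named list of gradients with
# respect to each branch's PILO output. Returns a flat named gradient list
# aligned with collect_params(gen).
gen_backward <- function(gen, cache, dmaps) {
  cfg <- gen$cfg
  S <- cfg$stages
  sd_ <- cfg$shared_depth
  sl <- cfg$leaky_slope
  grads <- list()
  d_shared <- lapply(cache$shared_acts, function(a) array(0, dim = dim(a)))

  for (kind in cfg$map_kinds) {
    br <- gen$branches[[kind]]
    bc <- cache$branches[[kind]]
    acts <- bc$acts
    d_acts <- lapply(acts, function(a) array(0, dim = dim(a)))

    g <- layer_bwd(br$pilo, bc$pilo, dmaps[[kind]], sl)
    grads[[paste0("branches/", kind, "/pilo.w")]] <- g$dw
    grads[[paste0("branches/", kind, "/pilo.b")]] <- g$db
    dy <- split_channels(g$dx, 1)$a * 0.5    # d/d(tanh out) of (t+1)/2

    for (j in S:1) {
      g <- layer_bwd(br$dec[[j]], bc$dec[[j]], dy, sl)
      grads[[paste0("branches/", kind, "/dec/", j, ".w")]] <- g$dw
      grads[[paste0("branches/", kind, "/dec/", j, ".b")]] <- g$db
      if (j == 1) {
        d_acts[[S]] <- d_acts[[S]] + g$dx
      } else {
        sp <- split_channels(g$dx, dim(g$dx)[3] - dim(acts[[S - j + 1]])[3])
        dy <- sp$a
        d_acts[[S - j + 1]] <- d_acts[[S - j + 1]] + sp$b
      }
    }

    for (j in (S - sd_):1) {
      s <- sd_ + j
      g <- layer_bwd(br$enc[[j]], bc$enc[[j]], d_acts[[s]], sl)
      grads[[paste0("branches/", kind, "/enc/", j, ".w")]] <- g$dw
      grads[[paste0("branches/", kind, "/enc/", j, ".b")]] <- g$db
      d_acts[[s - 1]] <- d_acts[[s - 1]] + g$dx
    }
    for (i in seq_len(sd_)) {
      d_shared[[i]] <- d_shared[[i]] + d_acts[[i]]
    }
  }

  dcur <- NULL
  for (i in sd_:1) {
    dy <- d_shared[[i]]
    if (!is.null(dcur)) dy <- dy + dcur
    g <- layer_bwd(gen$shared[[i]], cache$shared_caches[[i]], dy, sl)
    grads[[paste0("shared/", i, ".w")]] <- g$dw
    grads[[paste0("shared/", i, ".b")]] <- g$db
    dcur <- g$dx
  }
  grads
}

#' Discriminator forward pass
#'
#' @param disc a `ctpgan_discriminator`
#' @param x 4-channel paired input, dim (H, W, input_channels + 1, N)
#' @param keep_cache retain activations for a backward pass
#' @param norm_kind override the normalization kind
#' @return list with `y` (patch probability tensor, values in (0,1)) and,
#'   if requested, `cache`
#' @export
disc_forward <- function(disc, x, keep_cache = FALSE, norm_kind = NULL) {
  cfg <- disc$cfg
  d <- tensor_dim(x)
  nk <- if (is.null(norm_kind)) resolve_norm_kind(cfg, d[4]) else norm_kind
  caches <- vector("list", length(disc$layers))
  h <- x
  for (i in seq_along(disc$layers)) {
    lf <- layer_fwd(disc$layers[[i]], h, nk, cfg$leaky_slope)
    h <- lf$y
    caches[[i]] <- lf$cache
  }
  out <- list(y = h)
  if (keep_cache) out$cache <- list(norm_kind = nk, layers = caches)
  out
}

disc_backward <- function(disc, cache, dy) {
  grads <- list()
  for (i in rev(seq_along(disc$layers))) {
    g <- layer_bwd(disc$layers[[i]], cache$layers[[i]], dy,
                   disc$cfg$leaky_slope)
    grads[[paste0("layers/", i, ".w")]] <- g$dw
    grads[[paste0("layers/", i, ".b")]] <- g$db
    dy <- g$dx
  }
  list(grads = grads, dx = dy)
}

# ---- parameter accounting ---------------------------------------------

#' Normalization layer with learnable affine parameters
#'
#' Constructor for an affine (scale + shift per channel) normalization
#' block. The default generator/discriminator ledger uses non-affine
#' normalization (this is what reconciles the published parameter totals);
#' the constructor exists so alternative ledgers can be counted.
#'
#' @param channels number of channels
#' @return a countable `norm` node with `gamma`/`beta` vectors
#' @export
new_affine_norm <- function(channels) {
  list(type = "norm", gamma = rep(1, channels), beta = rep(0, channels))
}

collect_all_params <- function(node, path = character()) {
  if (is.list(node) && !is.null(node$type)) {
    if (node$type %in% c("conv", "tconv")) {
      out <- list(node$w, node$b)
      names(out) <- paste(paste(path, collapse = "/"), c("w", "b"),
                          sep = ".")
      return(out)
    }
    if (node$type == "norm") {
      out <- list(node$gamma, node$beta)
      names(out) <- paste(paste(path, collapse = "/"),
                          c("gamma", "beta"), sep = ".")
      return(out)
    }
  }
  if (is.list(node)) {
    out <- list()
    nm <- names(node)
    for (i in seq_along(node)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_all_params(node[[i]], c(path, key)))
    }
    return(out)
  }
  list()
}

#' Count trainable parameters
#'
#' Sums every trainable scalar (convolution weights and biases, affine
#' normalization parameters where present) in a network handle, a single
#' layer, or any nested list of them.
#'
#' @param handle a generator, discriminator, list of discriminators, layer,
#'   or nested list
#' @return total count (numeric scalar)
#' @seealso [parameter_ledger()] for the per-block breakdown
#' @export
count_parameters <- function(handle) {
  ps <- collect_all_params(handle)
  if (!length(ps)) return(0)
  sum(vapply(ps, length, numeric(1)))
}

#' Per-block parameter report
#'
#' @inheritParams count_parameters
#' @return data.frame with one row per weight/bias block and its size
#' @export
parameter_ledger <- function(handle) {
  ps <- collect_all_params(handle)
  data.frame(block = names(ps),
             params = vapply(ps, length, numeric(1)),
             row.names = NULL)
}

#' Theoretical receptive field of a convolution stack
#'
#' Evaluates the recurrence `RF <- RF + (k - 1) * prod(previous strides)`
#' analytically over the given stages.
#'
#' @param stages two-column matrix (kernel, stride), or a list of
#'   length-2 vectors
#' @return receptive field in input pixels per side
#' @export
receptive_field <- function(stages) {
  if (is.list(stages)) {
    if (!length(stages)) stop("need at least one stage")
    stages <- do.call(rbind, stages)
  }
  stages <- as.matrix(stages)
  if (nrow(stages) < 1) stop("need at least one stage")
  rf <- 1
  sprod <- 1
  for (i in seq_len(nrow(stages))) {
    rf <- rf + (unname(stages[i, 1]) - 1) * sprod
    sprod <- sprod * unname(stages[i, 2])
  }
  rf
}

#' Convolution geometry of the PatchGAN discriminator
#'
#' @return two-column matrix of (kernel, stride) for the five stages
#' @export
patchgan_stages <- function() {
  cbind(kernel = rep(4, 5), stride = c(2, 2, 2, 1, 1))
}

# ---- PILO --------------------------------------------------------------

#' Apply a PILO output layer
#'
#' Consumes the 4-channel concatenation of a synthesized perfusion channel
#' ([0,1] map space) and the 3-channel NCCT input, and emits the final
#' 1-channel map.
#'
#' @param branch_output tensor (H, W, 1, N) or matrix, the branch output in
#'   [0,1] map space
#' @param ncct3 tensor (H, W, 3, N) or (H, W, 3) pseudo-RGB input
#' @param pilo a PILO layer (e.g. `gen$branches$cbf$pilo`)
#' @return tensor (H, W, 1, N)
#' @export
pilo_forward <- function(branch_output, ncct3, pilo) {
  if (length(dim(branch_output)) == 2) {
    branch_output <- array(branch_output, dim = c(dim(branch_output), 1, 1))
  }
  if (length(dim(ncct3)) == 3) {
    ncct3 <- array(ncct3, dim = c(dim(ncct3), 1))
  }
  layer_fwd(pilo, concat_channels(branch_output, ncct3), "instance")$y
}

#' Rescale PILO input-channel weights
#'
#' Multiplies the weight slice of the synthesized-perfusion input channel
#' by `alpha_perf` and the slices of the three NCCT channels by
#' `alpha_anat`; `(1, 1)` is the identity. Accepts either a single PILO
#' layer or a whole generator (all four branches rescaled).
#'
#' @param x a PILO layer or `ctpgan_generator`
#' @param alpha_perf,alpha_anat nonnegative scale factors
#' @return the rescaled object
#' @export
pilo_rescale <- function(x, alpha_perf = 1, alpha_anat = 1) {
  if (alpha_perf < 0 || alpha_anat < 0) stop("alphas must be nonnegative")
  scale_one <- function(p) {
    p$w[, , , 1] <- p$w[, , , 1] * alpha_perf
    p$w[, , , 2:dim(p$w)[4]] <- p$w[, , , 2:dim(p$w)[4]] * alpha_anat
    p
  }
  if (inherits(x, "ctpgan_generator")) {
    for (kind in names(x$branches)) {
      x$branches[[kind]]$pilo <- scale_one(x$branches[[kind]]$pilo)
    }
    x
  } else {
    scale_one(x)
  }
}

# ---- checkpoints -------------------------------------------------------

#' Save a generator (and optional discriminators) checkpoint
#'
#' Writes a JSON architecture manifest sufficient to rebuild the networks,
#' plus the weight arrays.
#'
#' @param gen a `ctpgan_generator`
#' @param dir output directory (created if missing)
#' @param discs optional named list of discriminators
#' @return `dir`, invisibly
#' @export
save_checkpoint <- function(gen, dir, discs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ctpgan", config = unclass(gen$cfg),
                   seed = gen$seed,
                   has_discriminators = !is.null(discs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(collect_params(gen), file.path(dir, "generator_params.rds"))
  if (!is.null(discs)) {
    saveRDS(lapply(discs, collect_params),
            file.path(dir, "discriminator_params.rds"))
  }
  invisible(dir)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param dir checkpoint directory
#' @return list with `generator` and (if present) `discriminators`
#' @export
load_checkpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(network_config, manifest$config[
    c("image_size", "input_channels", "map_count", "base_width",
      "shared_depth", "kernel", "stride", "padding", "leaky_slope",
      "norm_kind", "pilo_kernel", "init_sd")])
  gen <- build_generator(cfg, seed = manifest$seed)
  gen <- assign_params(gen, readRDS(file.path(dir, "generator_params.rds")))
  out <- list(generator = gen)
  dpath <- file.path(dir, "discriminator_params.rds")
  if (file.exists(dpath)) {
    dp <- readRDS(dpath)
    discs <- build_discriminators(cfg, seed = manifest$seed)
    for (kind in names(dp)) {
      discs[[kind]] <- assign_params(discs[[kind]], dp[[kind]])
    }
    out$discriminators <- discs
  }
  out
}
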