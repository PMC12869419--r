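# Adversarial training: per iteration the four discriminators are updated
# on real and generated pairs and then frozen while the generator is
# updated on the combined objective (adversarial + lambda1 L1 +
# lambda2 extrema + lambda3 multimodal). Adam for all networks, constant
# learning rate.

#' Training configuration
#'
#' @param epochs training epochs
#' @param batch_size samples per iteration (batch normalization is used
#'   when > 1, instance normalization otherwise)
#' @param lr constant Adam learning rate for generator and discriminators
#' @param beta1,beta2 Adam moment decay rates
#' @param val_size validation slices held out at the image level
#' @param seed master seed: data split, shuffling, weight initialization
#' @param checkpoint_every write a checkpoint every this many epochs
#'   (0 disables)
#' @param checkpoint_dir checkpoint directory
#' @param loss_weights a [loss_weights()]
#' @param network a [network_config()]
#' @param log_file optional JSONL path receiving one loss report per
#'   iteration
#' @param verbose print per-epoch progress
#' @return a `ctpgan_train_config` list
#' @export
train_config <- function(epochs = 50, batch_size = 8, lr = 1e-4,
                         beta1 = 0.5, beta2 = 0.999, val_size = 100,
                         seed = 1, checkpoint_every = 0,
                         checkpoint_dir = NULL,
                         loss_weights = ctpgan::loss_weights(),
                         network = network_config(), log_file = NULL,
                         verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2,
                 val_size = as.integer(val_size), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 loss_weights = loss_weights, network = network,
                 log_file = log_file, verbose = verbose),
            class = "ctpgan_train_config")
}

assemble_batch <- function(samples, idx, stats) {
  H <- nrow(samples[[idx[1]]]$ncct3)
  B <- length(idx)
  x <- array(0, dim = c(H, H, 3, B))
  real <- lapply(stats::setNames(MAP_KINDS, MAP_KINDS),
                 function(k) array(0, dim = c(H, H, 1, B)))
  masks <- vector("list", B)
  for (b in seq_along(idx)) {
    s <- samples[[idx[b]]]
    x[, , , b] <- s$ncct3
    for (k in MAP_KINDS) real[[k]][, , 1, b] <- s$maps[[k]]
    masks[[b]] <- s$brain_mask
  }
  list(x = standardize_ncct(x, stats), real = real, masks = masks, B = B)
}

# auxiliary (non-adversarial) loss values and the combined gradient with
# respect to each generated map
gen_loss_terms <- function(fake, real, masks, w) {
  N <- length(fake)
  B <- dim(fake[[1]])[4]
  l1v <- exv <- 0
  dmaps <- list()
  for (m in names(fake)) {
    g <- fake[[m]]; r <- real[[m]]
    l1v <- l1v + mean(abs(g - r))
    dm <- w$lambda1 * l1_grad(g, r) / N
    for (b in seq_len(B)) {
      gb <- g[, , 1, b]; rb <- r[, , 1, b]; mb <- masks[[b]]
      exv <- exv + extrema_loss(gb, rb, mb) / (N * B)
      if (w$lambda2 > 0) {
        dm[, , 1, b] <- dm[, , 1, b] +
          w$lambda2 * extrema_grad(gb, rb, mb) / (N * B)
      }
    }
    dmaps[[m]] <- dm
  }
  mmv <- 0
  for (b in seq_len(B)) {
    cb <- fake$cbf[, , 1, b]; mt <- fake$mtt[, , 1, b]
    cv <- real$cbv[, , 1, b]; mb <- masks[[b]]
    mmv <- mmv + multimodal_loss(cb, mt, cv, mb, w$mml_scale) / B
    if (w$lambda3 > 0) {
      mg <- multimodal_grad(cb, mt, cv, mb, w$mml_scale)
      dmaps$cbf[, , 1, b] <- dmaps$cbf[, , 1, b] +
        w$lambda3 * mg$d_cbf / B
      dmaps$mtt[, , 1, b] <- dmaps$mtt[, , 1, b] +
        w$lambda3 * mg$d_mtt / B
    }
  }
  list(l1 = l1v / N, extrema = exv, multimodal = mmv, dmaps = dmaps)
}

#' Train the multitask GAN
#'
#' @param data output of [build_training_set()] (list with `samples` and
#'   `stats`), or a plain list of paired slices
#' @param config a [train_config()]
#' @return a `ctpgan_fit` object: generator, discriminators, per-iteration
#'   and per-epoch loss history, configuration and input statistics
#' @export
ctp_train <- function(data, config = train_config()) {
  samples <- if (!is.null(data$samples)) data$samples else data
  if (!length(samples)) stop("empty dataset")
  stats <- if (!is.null(data$stats)) data$stats else {
    pool <- unlist(lapply(samples, function(s) as.numeric(s$ncct3)))
    list(mean = mean(pool), sd = stats::sd(pool))
  }
  n <- length(samples)
  if (config$val_size >= n) {
    stop("val_size must be smaller than the dataset")
  }
  w <- config$loss_weights
  cfg <- config$network
  N <- length(cfg$map_kinds)

  val_idx <- with_seed(config$seed, sample.int(n, config$val_size))
  train_idx <- setdiff(seq_len(n), val_idx)
  val_samples <- samples[val_idx]

  gen <- build_generator(cfg, seed = config$seed)
  discs <- build_discriminators(cfg, seed = config$seed + 1000L)
  adamG <- adam_init(collect_params(gen))
  adamD <- lapply(discs, function(d) adam_init(collect_params(d)))

  log_con <- NULL
  if (!is.null(config$log_file)) {
    log_con <- file(config$log_file, open = "wt")
    on.exit(close(log_con), add = TRUE)
  }

  val_history <- list()
  record_val <- function(epoch) {
    v <- eval_objective(gen, discs, val_samples, w, stats,
                        config$batch_size)
    val_history[[length(val_history) + 1]] <<- c(epoch = epoch, v)
  }
  record_val(0)

  iter_history <- list()
  it <- 0L
  for (epoch in seq_len(config$epochs)) {
    order <- with_seed(config$seed * 10000L + epoch,
                       sample(train_idx))
    starts <- seq(1, length(order), by = config$batch_size)
    for (s0 in starts) {
      idx <- order[s0:min(s0 + config$batch_size - 1, length(order))]
      bt <- assemble_batch(samples, idx, stats)
      nk <- resolve_norm_kind(cfg, bt$B)

      gf <- gen_forward(gen, bt$x, keep_cache = TRUE, norm_kind = nk)
      fake <- gf$maps

      # --- discriminator updates (generator frozen)
      gan_D <- 0
      for (m in cfg$map_kinds) {
        rin <- concat_channels(bt$x, bt$real[[m]])
        fin <- concat_channels(bt$x, fake[[m]])
        rf <- disc_forward(discs[[m]], rin, keep_cache = TRUE,
                           norm_kind = nk)
        ff <- disc_forward(discs[[m]], fin, keep_cache = TRUE,
                           norm_kind = nk)
        dr <- clamp01(rf$y, w$eps); df <- clamp01(ff$y, w$eps)
        gan_D <- gan_D + (-mean(log(dr)) - mean(log(1 - df))) / N
        P <- length(dr)
        ddr <- array(ifelse(rf$y > w$eps & rf$y < 1 - w$eps,
                            -1 / (dr * P), 0), dim = dim(dr))
        ddf <- array(ifelse(ff$y > w$eps & ff$y < 1 - w$eps,
                            1 / ((1 - df) * P), 0), dim = dim(df))
        gR <- disc_backward(discs[[m]], rf$cache, ddr)$grads
        gF <- disc_backward(discs[[m]], ff$cache, ddf)$grads
        gsum <- gR
        for (k in names(gF)) gsum[[k]] <- gsum[[k]] + gF[[k]]
        ps <- collect_params(discs[[m]])
        st <- adam_step(ps, gsum[names(ps)], adamD[[m]], config$lr,
                        config$beta1, config$beta2)
        discs[[m]] <- assign_params(discs[[m]], st$params)
        adamD[[m]] <- st$state
      }

      # --- generator update (discriminators frozen)
      terms <- gen_loss_terms(fake, bt$real, bt$masks, w)
      dmaps <- terms$dmaps
      gan_G <- 0
      for (m in cfg$map_kinds) {
        fin <- concat_channels(bt$x, fake[[m]])
        ff <- disc_forward(discs[[m]], fin, keep_cache = TRUE,
                           norm_kind = nk)
        df <- clamp01(ff$y, w$eps)
        P <- length(df)
        if (w$non_saturating) {
          gan_G <- gan_G - mean(log(df)) / N
          ddf <- array(ifelse(ff$y > w$eps & ff$y < 1 - w$eps,
                              -1 / (df * P * N), 0), dim = dim(df))
        } else {
          gan_G <- gan_G + mean(log(1 - df)) / N
          ddf <- array(ifelse(ff$y > w$eps & ff$y < 1 - w$eps,
                              -1 / ((1 - df) * P * N), 0),
                       dim = dim(df))
        }
        dmap_gan <- disc_backward(discs[[m]], ff$cache, ddf)$dx
        dmaps[[m]] <- dmaps[[m]] +
          dmap_gan[, , cfg$input_channels + 1, , drop = FALSE]
      }
      grads <- gen_backward(gen, gf$cache, dmaps)
      ps <- collect_params(gen)
      st <- adam_step(ps, grads[names(ps)], adamG, config$lr,
                      config$beta1, config$beta2)
      gen <- assign_params(gen, st$params)
      adamG <- st$state

      it <- it + 1L
      rep_ <- total_objective(list(gan_G = gan_G, gan_D = gan_D,
                                   l1 = terms$l1,
                                   extrema = terms$extrema,
                                   multimodal = terms$multimodal), w)
      if (!all(vapply(rep_, is.finite, logical(1)))) {
        stop("non-finite loss at iteration ", it, ": ",
             paste(names(rep_), unlist(rep_), collapse = ", "))
      }
      iter_history[[it]] <- c(iteration = it, epoch = epoch,
                              unlist(unclass(rep_)))
      if (!is.null(log_con)) {
        writeLines(jsonlite::toJSON(as.list(iter_history[[it]]),
                                    auto_unbox = TRUE, digits = NA),
                   log_con)
      }
    }
    record_val(epoch)
    if (config$verbose) {
      v <- val_history[[length(val_history)]]
      message(sprintf("epoch %d: val total_G %.4f, val L1 %.4f",
                      epoch, v[["total_G"]], v[["l1"]]))
    }
    if (config$checkpoint_every > 0 &&
        epoch %% config$checkpoint_every == 0 &&
        !is.null(config$checkpoint_dir)) {
      save_checkpoint(gen, file.path(config$checkpoint_dir,
                                     sprintf("epoch_%03d", epoch)), discs)
    }
  }

  structure(list(generator = gen, discriminators = discs,
                 history = list(
                   iterations = as.data.frame(do.call(rbind, iter_history)),
                   validation = as.data.frame(do.call(rbind, val_history))),
                 config = config, stats = stats,
                 val_index = val_idx),
            class = "ctpgan_fit")
}

# generator-side objective on a sample set, no weight updates
eval_objective <- function(gen, discs, samples, w, stats, batch_size = 8) {
  n <- length(samples)
  if (!n) stop("empty validation set")
  cfg <- gen$cfg
  N <- length(cfg$map_kinds)
  tot <- c(gan_G = 0, l1 = 0, extrema = 0, multimodal = 0)
  starts <- seq(1, n, by = batch_size)
  wsum <- 0
  for (s0 in starts) {
    idx <- seq(s0, min(s0 + batch_size - 1, n))
    bt <- assemble_batch(samples, idx, stats)
    nk <- resolve_norm_kind(cfg, bt$B)
    fake <- gen_forward(gen, bt$x, norm_kind = nk)$maps
    gan_G <- 0
    for (m in cfg$map_kinds) {
      ff <- disc_forward(discs[[m]], concat_channels(bt$x, fake[[m]]),
                         norm_kind = nk)
      df <- clamp01(ff$y, w$eps)
      gan_G <- gan_G + (if (w$non_saturating) -mean(log(df))
                        else mean(log(1 - df))) / N
    }
    terms <- gen_loss_terms(fake, bt$real, bt$masks, w)
    tot <- tot + bt$B * c(gan_G = gan_G, l1 = terms$l1,
                          extrema = terms$extrema,
                          multimodal = terms$multimodal)
    wsum <- wsum + bt$B
  }
  tot <- tot / wsum
  total_G <- tot[["gan_G"]] + w$lambda1 * tot[["l1"]] +
    w$lambda2 * tot[["extrema"]] + w$lambda3 * tot[["multimodal"]]
  c(tot, total_G = total_G)
}

#' Generator validation loss
#'
#' Evaluates the full generator-side objective (no weight updates) on a
#' held-out sample set.
#'
#' @param fit a `ctpgan_fit`
#' @param samples list of paired slices
#' @return named vector: gan_G, l1, extrema, multimodal, total_G
#' @export
validate <- function(fit, samples) {
  stopifnot(inherits(fit, "ctpgan_fit"))
  eval_objective(fit$generator, fit$discriminators, samples,
                 fit$config$loss_weights, fit$stats,
                 fit$config$batch_size)
}

#' Median multimodal residual on held-out slices
#'
#' Median over slices of the in-mask mean `|CBF_hat * MTT_hat - CBV|` on
#' normalized maps — the quantity the multimodal loss drives down.
#'
#' @param fit a `ctpgan_fit`
#' @param samples paired slices
#' @return scalar residual
#' @export
multimodal_residual <- function(fit, samples) {
  cfg <- fit$generator$cfg
  res <- vapply(samples, function(s) {
    x <- standardize_ncct(array(s$ncct3, dim = c(dim(s$ncct3), 1)),
                          fit$stats)
    maps <- gen_forward(fit$generator, x, norm_kind = "instance")$maps
    multimodal_loss(maps$cbf[, , 1, 1], maps$mtt[, , 1, 1],
                    s$maps$cbv, s$brain_mask)
  }, numeric(1))
  stats::median(res)
}

#' Synthesize perfusion volumes from an NCCT volume
#'
#' Runs the generator at every admissible axial position (those with both
#' +/- offset neighbors; boundary slices are skipped and reported in the
#' `skipped` attribute), and denormalizes the outputs to physical units.
#'
#' @param fit a `ctpgan_fit`
#' @param ncct HU volume, dim (H, W, Z)
#' @param spacing axial spacing in mm
#' @param offset_mm pseudo-RGB offset in mm
#' @param alphas length-2 vector (alpha_perf, alpha_anat) applied to the
#'   PILO layers at inference
#' @param window a [window_spec()]
#' @param batch_size slices per generator pass
#' @return list with `positions` (axial indices) and the four predicted
#'   volumes in physical units
#' @export
infer_volume <- function(fit, ncct, spacing = 1, offset_mm = 4,
                         alphas = c(1, 1), window = window_spec(),
                         batch_size = 8) {
  cfg <- fit$generator$cfg
  Z <- dim(ncct)[3]
  positions <- admissible_positions(Z, offset_mm, spacing)
  if (!length(positions)) stop("volume too thin for the pseudo-RGB offset")
  gen <- pilo_rescale(fit$generator, alphas[1], alphas[2])
  win <- window_hu(ncct, window)
  size <- cfg$image_size

  strip_failures <- integer(0)
  slices <- lapply(positions, function(z) {
    n3 <- stack_pseudo_rgb(win, z, offset_mm, spacing)
    mask <- tryCatch(skull_strip(n3[, , 2]), error = function(e) {
      strip_failures <<- c(strip_failures, z)
      matrix(TRUE, nrow(n3), ncol(n3))
    })
    n3 <- resize_to(n3, size, "bilinear")
    mask <- resize_to(mask, size, "nearest")
    for (ch in 1:3) n3[, , ch] <- n3[, , ch] * mask
    n3
  })
  if (length(strip_failures)) {
    warning("skull stripping failed at slice(s) ",
            paste(strip_failures, collapse = ", "),
            "; using the full frame there")
  }

  out <- lapply(stats::setNames(MAP_KINDS, MAP_KINDS),
                function(k) array(0, dim = c(size, size,
                                             length(positions))))
  starts <- seq(1, length(positions), by = batch_size)
  for (s0 in starts) {
    idx <- seq(s0, min(s0 + batch_size - 1, length(positions)))
    x <- array(0, dim = c(size, size, 3, length(idx)))
    for (b in seq_along(idx)) x[, , , b] <- slices[[idx[b]]]
    x <- standardize_ncct(x, fit$stats)
    maps <- gen_forward(gen, x,
                        norm_kind = resolve_norm_kind(cfg,
                                                      length(idx)))$maps
    for (k in MAP_KINDS) {
      out[[k]][, , idx] <- denormalize_map(
        pmin(pmax(maps[[k]][, , 1, ], 0), 1), k)
    }
  }
  structure(c(list(positions = positions), out),
            skipped = setdiff(seq_len(Z), positions))
}

#' @export
print.ctpgan_fit <- function(x, ...) {
  cfg <- x$generator$cfg
  v <- x$history$validation
  cat("Multitask NCCT-to-CTP GAN fit\n")
  cat(sprintf("  image size %d, base width %d, %d encoder stages (%d shared)\n",
              cfg$image_size, cfg$base_width, cfg$stages, cfg$shared_depth))
  cat(sprintf("  generator parameters: %s; discriminators (x%d): %s\n",
              format(count_parameters(x$generator), big.mark = ","),
              length(x$discriminators),
              format(count_parameters(x$discriminators), big.mark = ",")))
  cat(sprintf("  trained %d epochs; validation L1 %.4f -> %.4f\n",
              max(v$epoch), v$l1[1], v$l1[nrow(v)]))
  invisible(x)
}

#' @export
summary.ctpgan_fit <- function(object, ...) {
  out <- list(config = object$config,
              validation = object$history$validation,
              final = object$history$validation[
                nrow(object$history$validation), ])
  class(out) <- "summary.ctpgan_fit"
  out
}

#' @export
print.summary.ctpgan_fit <- function(x, ...) {
  cat("Validation history (generator objective):\n")
  print(x$validation, row.names = FALSE)
  invisible(x)
}

#' Predict perfusion maps
#'
#' @param object a `ctpgan_fit`
#' @param newdata a HU volume (3D array; routed through [infer_volume()]),
#'   a single paired slice, or a list of paired slices
#' @param alphas PILO rescaling (alpha_perf, alpha_anat)
#' @param physical return physical units (TRUE) or normalized [0,1] maps
#' @param ... passed to [infer_volume()] for volume input
#' @return predicted maps; for slice input a (list of) named list of
#'   matrices
#' @export
predict.ctpgan_fit <- function(object, newdata, alphas = c(1, 1),
                               physical = TRUE, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3) {
    return(infer_volume(object, newdata, alphas = alphas, ...))
  }
  single <- !is.null(newdata$ncct3)
  slices <- if (single) list(newdata) else newdata
  gen <- pilo_rescale(object$generator, alphas[1], alphas[2])
  out <- lapply(slices, function(s) {
    x <- standardize_ncct(array(s$ncct3, dim = c(dim(s$ncct3), 1)),
                          object$stats)
    maps <- gen_forward(gen, x, norm_kind = "instance")$maps
    lapply(stats::setNames(MAP_KINDS, MAP_KINDS), function(k) {
      m <- maps[[k]][, , 1, 1]
      if (physical) denormalize_map(pmin(pmax(m, 0), 1), k) else m
    })
  })
  if (single) out[[1]] else out
}

#' Report auxiliary-loss magnitudes at initialization
#'
#' Computes the adversarial, L1, extrema and multimodal components on one
#' batch with a freshly initialized generator, as a calibration aid when
#' choosing loss weights.
#'
#' @param data output of [build_training_set()]
#' @param config a [train_config()]
#' @return named vector of component magnitudes
#' @export
calibrate_loss_weights <- function(data, config = train_config()) {
  samples <- if (!is.null(data$samples)) data$samples else data
  stats <- data$stats
  cfg <- config$network
  gen <- build_generator(cfg, seed = config$seed)
  discs <- build_discriminators(cfg, seed = config$seed + 1000L)
  idx <- seq_len(min(config$batch_size, length(samples)))
  eval_objective(gen, discs, samples[idx], config$loss_weights, stats,
                 config$batch_size)
}
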