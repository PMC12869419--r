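# Low-level network operations. Tensors are R arrays with dim (H, W, C, N);
# convolution weights dim (k, k, Cin, Cout), transposed-convolution weights
# dim (k, k, Cout, Cin). The convolution kernels live in src/conv_ops.cpp.

NORM_EPS <- 1e-5
LOG_EPS <- 1e-7

as_tensor <- function(x, H, W, C, N) {
  array(x, dim = c(H, W, C, N))
}

tensor_dim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

concat_channels <- function(a, b) {
  da <- tensor_dim(a); db <- tensor_dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- tensor_dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- normalization (no learnable affine: see parameter ledger in network.R)

norm_fwd <- function(x, kind) {
  d <- tensor_dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, nrow = HW)
  if (kind == "batch") {
    mcn <- colMeans(xm)
    ecn <- colMeans(xm^2)
    m <- rowMeans(matrix(mcn, C, N))
    v <- rowMeans(matrix(ecn, C, N)) - m^2
    mc <- rep(m, times = N); invc <- rep(1 / sqrt(v + NORM_EPS), times = N)
  } else {                           # instance: per (channel, sample)
    mc <- colMeans(xm)
    invc <- 1 / sqrt(colMeans(xm^2) - mc^2 + NORM_EPS)
  }
  xhat <- sweep(sweep(xm, 2, mc, "-"), 2, invc, "*")
  y <- array(xhat, dim = d)
  list(y = y, cache = list(xhat = xhat, invc = invc, kind = kind, d = d))
}

norm_bwd <- function(dy, cache) {
  d <- cache$d
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dym <- matrix(dy, nrow = HW)
  if (cache$kind == "batch") {
    mdy <- rep(rowMeans(matrix(colMeans(dym), C, N)), times = N)
    mdyx <- rep(rowMeans(matrix(colMeans(dym * cache$xhat), C, N)), times = N)
  } else {
    mdy <- colMeans(dym)
    mdyx <- colMeans(dym * cache$xhat)
  }
  dx <- sweep(dym, 2, mdy, "-") - sweep(cache$xhat, 2, mdyx, "*")
  array(sweep(dx, 2, cache$invc, "*"), dim = d)
}

# ---- activations

act_fwd <- function(x, act, slope = 0.2) {
  switch(act,
    none = list(y = x, cache = NULL),
    lrelu = {
      y <- pmax(x, 0) + slope * pmin(x, 0)
      list(y = y, cache = x >= 0)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = y)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = y)
    },
    stop("unknown activation: ", act))
}

act_bwd <- function(dy, act, cache, slope = 0.2) {
  switch(act,
    none = dy,
    lrelu = dy * ifelse(cache, 1, slope),
    tanh = dy * (1 - cache^2),
    sigmoid = dy * cache * (1 - cache))
}

# ---- layers: (transposed) convolution -> optional norm -> activation

new_layer <- function(type = c("conv", "tconv"), k, cin, cout, stride, pad,
                      norm = FALSE, act = "lrelu", init_sd = 0.02) {
  type <- match.arg(type)
  wdim <- if (type == "conv") c(k, k, cin, cout) else c(k, k, cout, cin)
  list(type = type,
       w = array(stats::rnorm(prod(wdim), 0, init_sd), dim = wdim),
       b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad),
       norm = norm, act = act)
}

layer_fwd <- function(layer, x, norm_kind = "batch", slope = 0.2) {
  z <- if (layer$type == "conv") {
    .conv_fwd(x, layer$w, layer$b, layer$stride, layer$pad)
  } else {
    .tconv_fwd(x, layer$w, layer$b, layer$stride, layer$pad)
  }
  ncache <- NULL
  if (layer$norm) {
    nf <- norm_fwd(z, norm_kind)
    z <- nf$y
    ncache <- nf$cache
  }
  af <- act_fwd(z, layer$act, slope)
  list(y = af$y, cache = list(x = x, norm = ncache, act = af$cache))
}

layer_bwd <- function(layer, cache, dy, slope = 0.2) {
  dz <- act_bwd(dy, layer$act, cache$act, slope)
  if (layer$norm) dz <- norm_bwd(dz, cache$norm)
  g <- if (layer$type == "conv") {
    .conv_bwd(cache$x, layer$w, dz, layer$stride, layer$pad)
  } else {
    .tconv_bwd(cache$x, layer$w, dz, layer$stride, layer$pad)
  }
  list(dx = g$dx, dw = g$dw, db = g$db)
}

layer_param_count <- function(layer) length(layer$w) + length(layer$b)

# ---- parameter flattening (for the Adam optimizer and checkpoints)

# Walk a nested handle structure collecting the w/b arrays of every layer.
# A "layer" is recognized by having a $type of "conv"/"tconv".
collect_params <- function(node, path = character()) {
  if (is.list(node) && !is.null(node$type) &&
      node$type %in% c("conv", "tconv")) {
    out <- list(node$w, node$b)
    names(out) <- paste(c(paste(path, collapse = "/")),
                        c("w", "b"), sep = ".")
    return(out)
  }
  if (is.list(node)) {
    out <- list()
    nm <- names(node)
    for (i in seq_along(node)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_params(node[[i]], c(path, key)))
    }
    return(out)
  }
  list()
}

# Write a flat named parameter list back into the nested handle.
assign_params <- function(node, flat, path = character()) {
  if (is.list(node) && !is.null(node$type) &&
      node$type %in% c("conv", "tconv")) {
    base <- paste(path, collapse = "/")
    node$w <- array(flat[[paste0(base, ".w")]], dim = dim(node$w))
    node$b <- as.numeric(flat[[paste0(base, ".b")]])
    return(node)
  }
  if (is.list(node)) {
    nm <- names(node)
    for (i in seq_along(node)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      node[[i]] <- assign_params(node[[i]], flat, c(path, key))
    }
  }
  node
}

adam_init <- function(flat_params) {
  list(m = lapply(flat_params, function(p) p * 0),
       v = lapply(flat_params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat_params, flat_grads, state,
                      lr = 1e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat_params)) {
    g <- flat_grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat_params[[k]] <- flat_params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = flat_params, state = state)
}

# run a block of code with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
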