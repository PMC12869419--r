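# Shared small fixtures, built in code.

tiny_lesion <- function(n = 64, ...) {
  lesion_spec(center = c((n + 1) / 2, (n + 1) / 2 + 0.2 * n),
              core_axes = c(0.06, 0.05) * n,
              penumbra_axes = c(0.10, 0.08) * n, ...)
}

tiny_phantom_spec <- function(seed = 11, lesion = NULL, image_size = 64,
                              slice_count = 3, ...) {
  phantom_spec(image_size = image_size, slice_count = slice_count,
               axial_spacing = 4, lesion = lesion, seed = seed, ...)
}

# naive direct convolution used as the oracle for the compiled kernels
naive_conv <- function(x, w, b, stride, pad) {
  d <- dim(x); k <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  for (n in seq_len(d[4])) for (co in seq_len(Cout)) {
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      patch <- xp[(i - 1) * stride + seq_len(k),
                  (j - 1) * stride + seq_len(k), , n, drop = FALSE]
      y[i, j, co, n] <- sum(as.vector(patch) *
                              as.vector(w[, , , co, drop = FALSE])) + b[co]
    }
  }
  y
}

rand_tensor <- function(H, W, C, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}
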