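# Loss terms: closed-form cases, loop oracles and analytic gradients.
# (The 100-batch 1e-12 oracle sweep and finite-difference suite is in the
# acceptance tests; here each operation gets its hand cases and
# properties.)

loop_l1 <- function(g, r) {
  s <- 0
  for (i in seq_along(g)) s <- s + abs(g[i] - r[i])
  s / length(g)
}

loop_mml <- function(cbf, mtt, cbv) {
  s <- 0
  for (i in seq_along(cbf)) s <- s + abs(cbf[i] * mtt[i] - cbv[i])
  s / length(cbf)
}

loop_extrema <- function(g, r) {
  nrm <- function(v) (v - min(v)) / (max(v) - min(v))
  w <- (nrm(r) - 0.5)^2
  h <- (nrm(g) - nrm(r))^2
  s <- 0
  for (i in seq_along(g)) s <- s + w[i] * h[i]
  s / length(g)
}

test_that("gan_loss reproduces closed forms and a patch-level oracle", {
  d5 <- matrix(0.5, 3, 3)
  gl <- gan_loss(d5, d5)
  expect_equal(gl$loss_D, 2 * log(2), tolerance = 1e-12)
  expect_equal(gl$loss_G, log(2), tolerance = 1e-12)

  perfect <- gan_loss(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_lt(perfect$loss_D, 1e-5)

  set.seed(30)
  dr <- matrix(runif(9, 0.1, 0.9), 3)
  df <- matrix(runif(9, 0.1, 0.9), 3)
  brute_D <- -(sum(log(dr)) / 9 + sum(log(1 - df)) / 9)
  expect_equal(gan_loss(dr, df)$loss_D, brute_D, tolerance = 1e-12)
  # averaging over four map kinds
  gl4 <- gan_loss(rep(list(dr), 4), rep(list(df), 4))
  expect_equal(gl4$loss_D, brute_D, tolerance = 1e-12)
  # saturating generator form
  expect_equal(gan_loss(dr, df, non_saturating = FALSE)$loss_G,
               mean(log(1 - df)), tolerance = 1e-12)
})

test_that("l1_loss matches its definition and the loop oracle", {
  set.seed(31)
  g <- matrix(runif(64, 0.1, 0.8), 8)
  expect_equal(l1_loss(g, g), 0)
  expect_equal(l1_loss(g + 0.1, g), 0.1, tolerance = 1e-12)
  r <- matrix(runif(64), 8)
  expect_equal(l1_loss(g, r), loop_l1(g, r), tolerance = 1e-12)
  expect_error(l1_loss(g, matrix(0, 4, 4)), "mismatch")
})

test_that("multimodal_loss is the literal normalized product residual", {
  ones <- matrix(1, 4, 4)
  expect_equal(multimodal_loss(ones, ones, ones), 0)
  expect_equal(multimodal_loss(ones * 0, ones, ones * 0.37), 0.37,
               tolerance = 1e-12)
  set.seed(32)
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  cv <- matrix(runif(64), 8)
  expect_equal(multimodal_loss(a, b, cv), loop_mml(a, b, cv),
               tolerance = 1e-12)
})

test_that("the extrema weight map emphasizes extremes and ignores affine scale", {
  w <- extrema_weight_map(c(0, 0.5, 1))
  expect_equal(w, c(0.25, 0, 0.25))
  set.seed(33)
  pm <- matrix(runif(64), 8)
  expect_equal(extrema_weight_map(2 * pm + 5), extrema_weight_map(pm),
               tolerance = 1e-12)
  expect_warning(w0 <- extrema_weight_map(matrix(1, 4, 4)), "constant")
  expect_true(all(w0 == 0))
})

test_that("extrema_loss vanishes on identity and affine transforms and matches the oracle", {
  set.seed(34)
  g <- matrix(runif(64), 8)
  expect_equal(extrema_loss(g, g), 0)
  expect_equal(extrema_loss(3 * g + 2, g), 0, tolerance = 1e-12)
  r <- matrix(runif(64), 8)
  expect_equal(extrema_loss(g, r), loop_extrema(g, r), tolerance = 1e-12)
})

test_that("relocating error onto extreme pixels increases the extrema loss", {
  r <- matrix(seq(0, 1, length.out = 25), 5)
  mid <- which.min(abs(r - 0.5))
  ext <- which.max(r)
  g_mid <- r; g_mid[mid] <- g_mid[mid] + 0.2
  g_ext <- r; g_ext[ext] <- g_ext[ext] + 0.2
  expect_gt(extrema_loss(g_ext, r), extrema_loss(g_mid, r))
})

test_that("nonnegativity holds and zeros identify the identity conditions", {
  set.seed(35)
  for (i in 1:20) {
    g <- matrix(runif(36), 6); r <- matrix(runif(36), 6)
    expect_gte(l1_loss(g, r), 0)
    expect_gte(extrema_loss(g, r), 0)
    expect_gte(multimodal_loss(g, r, matrix(runif(36), 6)), 0)
  }
})

test_that("total_objective composes the weighted terms", {
  w0 <- loss_weights(0, 0, 0)
  rep0 <- total_objective(list(gan_G = 0.8, gan_D = 1.2, l1 = 0.3,
                               extrema = 0.1, multimodal = 0.2), w0)
  expect_equal(rep0$total_G, 0.8)
  expect_equal(rep0$total_D, 1.2)
  # perfect generator, D at 0.5 everywhere
  gl <- gan_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  repp <- total_objective(list(gan_G = gl$loss_G, gan_D = gl$loss_D,
                               l1 = 0, extrema = 0, multimodal = 0),
                          loss_weights())
  expect_equal(repp$total_G, -log(0.5), tolerance = 1e-12)
  rep1 <- total_objective(list(gan_G = 0.7, gan_D = 1, l1 = 0.1,
                               extrema = 0, multimodal = 0),
                          loss_weights(100, 0, 0))
  expect_equal(rep1$total_G, 10.7)
  expect_error(loss_weights(-1), "nonnegative")
  expect_error(total_objective(list(gan_G = 1), loss_weights()), "missing")
})

test_that("masked losses use in-mask statistics", {
  set.seed(36)
  g <- matrix(runif(64), 8); r <- matrix(runif(64), 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  expect_equal(multimodal_loss(g, g, r, mask),
               mean(abs(g * g - r)[mask]), tolerance = 1e-12)
  ex_in <- extrema_loss(g[3:6, 3:6], r[3:6, 3:6])
  expect_equal(extrema_loss(g, r, mask), ex_in, tolerance = 1e-12)
})
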