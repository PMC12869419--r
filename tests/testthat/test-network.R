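# Architecture: parameter accounting, receptive field, shapes, sharing,
# PILO rescaling and checkpoints. The exact published totals are asserted
# in the acceptance suite.

test_that("count_parameters matches closed forms for single blocks", {
  set.seed(20)
  conv <- ctpgan:::new_layer("conv", 4, 3, 64, 2, 1)
  expect_equal(count_parameters(conv), 3 * 64 * 16 + 64)  # 3136
  expect_equal(count_parameters(new_affine_norm(128)), 256)
  expect_equal(count_parameters(list()), 0)
  gen <- build_generator(network_config(image_size = 32, base_width = 4))
  led <- parameter_ledger(gen)
  expect_equal(sum(led$params), count_parameters(gen))
})

test_that("receptive field recurrence reproduces the analytic values", {
  expect_equal(receptive_field(list(c(4, 2))), 4)
  expect_equal(receptive_field(patchgan_stages()), 70)
  expect_equal(receptive_field(matrix(1, nrow = 7, ncol = 2)), 1)
  expect_error(receptive_field(list()), "at least one")
})

test_that("generator halves the resolution to a 1x1 bottleneck and emits four maps", {
  cfg <- network_config(image_size = 32, base_width = 4, shared_depth = 2)
  gen <- build_generator(cfg, seed = 21)
  x <- rand_tensor(32, 32, 3, 2, seed = 21)
  f <- gen_forward(gen, x, keep_cache = TRUE, norm_kind = "instance")
  expect_named(f$maps, c("cbf", "cbv", "mtt", "ttp"))
  for (m in f$maps) {
    expect_equal(dim(m), c(32L, 32L, 1L, 2L))
    expect_true(all(is.finite(m)))
  }
  acts <- f$cache$branches$cbf$acts
  for (s in seq_along(acts)) {
    expect_equal(dim(acts[[s]])[1], 32L / 2L^s)
  }
  expect_equal(dim(acts[[cfg$stages]])[1:3],
               c(1L, 1L, tail(cfg$encoder_widths, 1)))
})

test_that("two builds with the same seed are identical; different seeds differ", {
  cfg <- network_config(image_size = 32, base_width = 4)
  expect_identical(build_generator(cfg, seed = 5),
                   build_generator(cfg, seed = 5))
  g1 <- build_generator(cfg, seed = 5)
  g2 <- build_generator(cfg, seed = 6)
  expect_false(identical(g1$shared[[1]]$w, g2$shared[[1]]$w))
})

test_that("shared weights steer all maps; branch weights only their own", {
  cfg <- network_config(image_size = 16, base_width = 4, shared_depth = 2)
  gen <- build_generator(cfg, seed = 22)
  x <- rand_tensor(16, 16, 3, 1, seed = 22)
  base <- gen_forward(gen, x, norm_kind = "instance")$maps
  perturb <- function(g, path_fun) {
    flat <- ctpgan:::collect_params(g)
    nm <- path_fun(names(flat))
    flat[[nm]] <- flat[[nm]] + 0.5
    ctpgan:::assign_params(g, flat)
  }
  g_sh <- perturb(gen, function(nms) grep("^shared/1", nms, value = TRUE)[1])
  out_sh <- gen_forward(g_sh, x, norm_kind = "instance")$maps
  for (m in names(base)) {
    expect_gt(max(abs(out_sh[[m]] - base[[m]])), 0)
  }
  g_br <- perturb(gen, function(nms)
    grep("^branches/mtt/dec", nms, value = TRUE)[1])
  out_br <- gen_forward(g_br, x, norm_kind = "instance")$maps
  expect_gt(max(abs(out_br$mtt - base$mtt)), 0)
  for (m in c("cbf", "cbv", "ttp")) {
    expect_equal(out_br[[m]], base[[m]])
  }
})

test_that("discriminator patch outputs are probabilities of the right size", {
  cfg <- network_config(image_size = 64, base_width = 8)
  d <- build_discriminator(cfg, seed = 23)
  y <- disc_forward(d, rand_tensor(64, 64, 4, 2, seed = 23),
                    norm_kind = "instance")$y
  expect_equal(dim(y)[1:2], c(6L, 6L))
  expect_true(all(y > 0 & y < 1))
})

test_that("PILO rescaling is the identity at (1,1) and zeroes the right channels", {
  cfg <- network_config(image_size = 16, base_width = 4)
  gen <- build_generator(cfg, seed = 24)
  pilo <- gen$branches$cbf$pilo
  set.seed(24)
  perf <- array(runif(16 * 16), c(16, 16, 1, 1))
  anat <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  base <- pilo_forward(perf, anat, pilo)
  expect_equal(pilo_forward(perf, anat, pilo_rescale(pilo, 1, 1)), base)

  p0 <- pilo_rescale(pilo, alpha_anat = 0)
  anat2 <- anat + array(rnorm(length(anat)), dim(anat))
  expect_equal(pilo_forward(perf, anat, p0), pilo_forward(perf, anat2, p0))

  pp <- pilo_rescale(pilo, alpha_perf = 0)
  perf2 <- perf + array(rnorm(length(perf)), dim(perf))
  expect_equal(pilo_forward(perf, anat, pp), pilo_forward(perf2, anat, pp))
  expect_error(pilo_rescale(pilo, -1, 1), "nonnegative")
})

test_that("checkpoints rebuild the generator bit-identically", {
  cfg <- network_config(image_size = 16, base_width = 4)
  gen <- build_generator(cfg, seed = 25)
  discs <- build_discriminators(cfg, seed = 26)
  dir <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(gen, dir, discs)
  lo <- load_checkpoint(dir)
  x <- rand_tensor(16, 16, 3, 1, seed = 27)
  expect_equal(gen_forward(lo$generator, x, norm_kind = "instance")$maps,
               gen_forward(gen, x, norm_kind = "instance")$maps)
  expect_identical(ctpgan:::collect_params(lo$discriminators$ttp),
                   ctpgan:::collect_params(discs$ttp))
  unlink(dir, recursive = TRUE)
})
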