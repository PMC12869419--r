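# Windowing, map normalization, stacking, skull stripping, resize and
# augmentation.

test_that("HU windowing maps the brain window linearly and clips outside", {
  w <- window_spec()
  expect_equal(window_hu(c(0, 40, 80), w), c(0, 0.5, 1))
  expect_equal(window_hu(2000, w), 1)     # skull saturates
  expect_equal(window_hu(-1000, w), 0)    # air clips to zero
  expect_error(window_spec(width = 0), "positive")
  expect_error(window_hu(c(1, NA)), "finite")
})

test_that("map normalization is the stated linear map and round-trips in range", {
  expect_equal(normalize_map(c(0, 30, 60), "cbf"), c(0, 0.5, 1))
  expect_equal(normalize_map(12, "mtt"), 1)
  expect_equal(normalize_map(30, "ttp"), 1)   # clipped above 25
  set.seed(11)
  for (k in names(map_ranges())) {
    r <- map_ranges()[[k]]
    v <- runif(50, r[1], r[2])
    expect_equal(denormalize_map(normalize_map(v, k), k), v,
                 tolerance = 1e-12)
  }
  expect_error(normalize_map(1, "flow"))
})

test_that("pseudo-RGB stacking picks the offset slices and rejects boundaries", {
  vol <- array(rep(seq_len(100), each = 4), c(2, 2, 100))
  s <- stack_pseudo_rgb(vol, z = 50, offset_mm = 4, spacing = 1)
  expect_equal(unique(as.vector(s[, , 1])), 46)
  expect_equal(unique(as.vector(s[, , 2])), 50)
  expect_equal(unique(as.vector(s[, , 3])), 54)
  cst <- array(7, c(2, 2, 20))
  s2 <- stack_pseudo_rgb(cst, 10, 4, 1)
  expect_true(all(s2 == 7))
  expect_error(stack_pseudo_rgb(vol, z = 2, offset_mm = 4, spacing = 1),
               "outside")
})

test_that("skull stripping recovers the phantom brain mask", {
  co <- sample_cohort(10, c(none = 0.5, mild_moderate = 0.3, severe = 0.2),
                      seed = 12, spec = tiny_phantom_spec())
  ious <- vapply(co, function(cs) {
    z <- 2
    sl <- window_hu(cs$ncct[, , z])
    m <- skull_strip(sl)
    truth <- cs$brain_mask[, , z]
    expect_true(all(sl[m] < 1))      # strictly inside the skull ring
    sum(m & truth) / sum(m | truth)
  }, numeric(1))
  expect_true(all(ious > 0.95))
  expect_error(skull_strip(matrix(0, 16, 16)), "empty")
})

test_that("resize is idempotent, constant-preserving and mean-preserving on 2x downsampling", {
  set.seed(13)
  img <- matrix(runif(256 * 256), 256)
  expect_equal(resize_to(img, 256), img)
  cst <- matrix(3.5, 512, 512)
  expect_true(all(abs(resize_to(cst, 256) - 3.5) < 1e-12))
  checker <- outer(1:512, 1:512, function(i, j) (i + j) %% 2)
  down <- resize_to(checker, 256)
  expect_equal(mean(down), mean(checker), tolerance = 1e-6)
  m <- matrix(c(TRUE, FALSE), 8, 8)
  expect_type(resize_to(m, 4, "nearest"), "logical")
})

test_that("augmentation applies one transform jointly and identity/involution hold", {
  p <- make_phantom(tiny_phantom_spec(seed = 14, lesion = tiny_lesion()))
  s <- paired_slices_from_phantom(p)[[1]]
  idt <- list(flip = FALSE, theta = 0, tx = 0, ty = 0)
  s_id <- augment(s, transform = idt)
  expect_equal(s_id$ncct3, s$ncct3)
  expect_equal(s_id$maps, s$maps)

  fl <- list(flip = TRUE, theta = 0, tx = 0, ty = 0)
  s2 <- augment(augment(s, transform = fl), transform = fl)
  expect_equal(s2$ncct3, s$ncct3)
  expect_equal(s2$brain_mask, s$brain_mask)

  sh <- list(flip = FALSE, theta = 0, tx = 30, ty = 0)
  s3 <- augment(s, transform = sh)
  expect_lte(sum(s3$brain_mask), sum(s$brain_mask))

  # all 7 channels and the mask see the same draw
  set.seed(15)
  s4 <- augment(s, aug_spec(p_hflip = 1, rotation_range = 10,
                            translation_range = 5))
  tr <- s4$transform
  expect_equal(s4$maps$cbf,
               ctpgan:::apply_transform(s$maps$cbf, tr$flip, tr$theta,
                                        tr$tx, tr$ty, "bilinear"))
})

test_that("augmentation commutes with masking under nearest-neighbor sampling", {
  p <- make_phantom(tiny_phantom_spec(seed = 16))
  img <- window_hu(p$ncct[, , 2])
  mask <- p$brain_mask[, , 2]
  tr <- list(flip = TRUE, theta = 7, tx = 3, ty = -2)
  a <- ctpgan:::apply_transform(img * mask, tr$flip, tr$theta, tr$tx,
                                tr$ty, "nearest")
  b <- ctpgan:::apply_transform(img, tr$flip, tr$theta, tr$tx, tr$ty,
                                "nearest") *
    ctpgan:::apply_transform(mask, tr$flip, tr$theta, tr$tx, tr$ty,
                             "nearest")
  expect_equal(a, b)
})

test_that("the center pseudo-RGB channel equals the windowed source slice", {
  p <- make_phantom(tiny_phantom_spec(seed = 17))
  s <- paired_slices_from_phantom(p)[[1]]
  win <- window_hu(p$ncct[, , s$z_index])
  expect_equal(s$ncct3[, , 2], win * s$brain_mask)
})

test_that("build_training_set emits the right count, is reproducible, and z-scores", {
  co <- sample_cohort(3, c(none = 1, mild_moderate = 0, severe = 0),
                      seed = 18, spec = tiny_phantom_spec())
  a <- aug_spec(rotation_range = 10, translation_range = 5,
                copies_per_slice = 3)
  t1 <- build_training_set(co, a, seed = 19)
  t2 <- build_training_set(co, a, seed = 19)
  # 3 cases x 1 admissible slice x 3 copies
  expect_length(t1$samples, 9)
  expect_identical(t1, t2)
  pool <- unlist(lapply(t1$samples,
                        function(s) standardize_ncct(s$ncct3, t1$stats)))
  expect_equal(mean(pool), 0, tolerance = 1e-6)
  expect_equal(sd(pool), 1, tolerance = 1e-3)
  expect_error(build_training_set(list()), "empty")
})

test_that("admissible positions follow the slices - 2*offset rule", {
  expect_length(admissible_positions(161, 4, 1), 153)
  expect_equal(admissible_positions(5, 4, 4), 2:4)
  expect_length(admissible_positions(8, 4, 1), 0)
})
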