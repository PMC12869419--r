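# SSIM/UQI metrics, bounding box, mismatch ratio and cohort evaluation.

# direct sliding-window implementations used as oracles
oracle_metric <- function(x, y, k2, c1, c2, uqi_mode = FALSE) {
  n <- nrow(k2)
  vals <- c()
  for (i in 1:(nrow(x) - n + 1)) {
    for (j in 1:(ncol(x) - n + 1)) {
      px <- x[i:(i + n - 1), j:(j + n - 1)]
      py <- y[i:(i + n - 1), j:(j + n - 1)]
      mx <- sum(k2 * px); my <- sum(k2 * py)
      vx <- sum(k2 * px^2) - mx^2
      vy <- sum(k2 * py^2) - my^2
      cxy <- sum(k2 * px * py) - mx * my
      if (uqi_mode) {
        vals <- c(vals, (4 * cxy * mx * my) /
                    ((vx + vy) * (mx^2 + my^2)))
      } else {
        vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                    ((mx^2 + my^2 + c1) * (vx + vy + c2)))
      }
    }
  }
  mean(vals)
}

test_that("brain bounding box is tight", {
  full <- matrix(TRUE, 5, 7)
  expect_equal(brain_bounding_box(full), list(row = c(1, 5), col = c(1, 7)))
  single <- matrix(FALSE, 6, 6); single[3, 4] <- TRUE
  expect_equal(brain_bounding_box(single),
               list(row = c(3, 3), col = c(4, 4)))
  p <- make_phantom(tiny_phantom_spec(seed = 40, image_size = 32))
  box <- brain_bounding_box(p$brain_mask[, , 2])
  expect_gt(box$row[1], 1); expect_lt(box$row[2], 32)
  expect_error(brain_bounding_box(matrix(FALSE, 3, 3)), "empty")
})

test_that("ssim and uqi equal 1 on identical images and are symmetric", {
  set.seed(41)
  x <- matrix(runif(20 * 20), 20)
  y <- matrix(runif(20 * 20), 20)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(uqi(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_equal(uqi(x, y), uqi(y, x), tolerance = 1e-12)
  cst <- matrix(0.4, 16, 16)
  expect_equal(ssim(cst, cst), 1)   # stabilizers guard 0/0
  expect_equal(uqi(cst, cst), 1)
  expect_error(ssim(x, y[1:10, 1:10]), "mismatch")
  expect_error(ssim(x[1:8, 1:8], y[1:8, 1:8]), "smaller")
})

test_that("ssim and uqi match direct sliding-window oracles", {
  set.seed(42)
  x <- matrix(runif(256), 16)
  y <- pmin(pmax(x + rnorm(256, 0, 0.2), 0), 1)
  g1 <- ctpgan:::gaussian_kernel_1d(11, 1.5)
  expect_equal(ssim(x, y), oracle_metric(x, y, outer(g1, g1),
                                         0.01^2, 0.03^2),
               tolerance = 1e-10)
  u1 <- rep(1 / 8, 8)
  expect_equal(uqi(x, y), oracle_metric(x, y, outer(u1, u1), 0, 0,
                                        uqi_mode = TRUE),
               tolerance = 1e-10)
  # binary pair against the oracle (the x vs 1-x hand case)
  xb <- matrix(rep(c(0, 1), length.out = 256), 16)
  expect_equal(ssim(xb, 1 - xb),
               oracle_metric(xb, 1 - xb, outer(g1, g1), 0.01^2, 0.03^2),
               tolerance = 1e-10)
})

test_that("uqi is ssim with vanishing stabilizers on a uniform window", {
  set.seed(43)
  x <- matrix(runif(256, 0.2, 0.8), 16)
  y <- matrix(runif(256, 0.2, 0.8), 16)
  expect_equal(ssim(x, y, window = "uniform", size = 8,
                    c1 = 1e-14, c2 = 1e-14),
               uqi(x, y), tolerance = 1e-6)
})

test_that("mismatch ratio and severity classification follow the clinical thresholds", {
  z <- array(FALSE, c(4, 4, 2))
  expect_equal(mismatch_ratio(z, z), 0)
  core <- z; core[1:2, 1:2, 1] <- TRUE      # 4 voxels
  pen <- z; pen[1:2, 1:4, 1] <- TRUE; pen[1:2, 1, 2] <- TRUE  # 10 voxels
  expect_equal(mismatch_ratio(core, pen), 0.4)
  expect_equal(mismatch_ratio(pen, pen), 1)
  expect_equal(mismatch_ratio(core, z), Inf)
  expect_error(mismatch_ratio(core, array(FALSE, c(2, 2, 2))), "mismatch")

  expect_equal(as.character(classify_severity(0)), "none")
  expect_equal(as.character(classify_severity(0.5)), "mild_moderate")
  expect_equal(as.character(classify_severity(0.51)), "severe")
  expect_equal(as.character(classify_severity(Inf)), "severe")
  expect_error(classify_severity(-0.1), "nonnegative")
})

test_that("derived ischemia masks recover the phantom lesion classes", {
  sp <- tiny_phantom_spec(seed = 44, lesion = tiny_lesion(),
                          noise_sd = 0, map_noise_sd = 0)
  p <- make_phantom(sp)
  dm <- derive_ischemia_masks(p$cbf, p$ttp, p$brain_mask)
  expect_true(all(dm$core_mask[p$core_mask]))
  expect_false(any(dm$core_mask & !p$core_mask))
})

test_that("evaluate_cohort scores perfect predictions as 1 with correct strata", {
  co <- sample_cohort(6, c(none = 0.4, mild_moderate = 0.3, severe = 0.3),
                      seed = 45, spec = tiny_phantom_spec())
  pred <- lapply(co, function(cs)
    lapply(cs[c("cbf", "cbv", "mtt", "ttp")], identity))
  names(pred) <- vapply(co, function(x) x$case_id, character(1))
  rep <- evaluate_cohort(pred, co)
  expect_true(all(abs(rep$ssim - 1) < 1e-9))
  expect_true(all(abs(rep$uqi - 1) < 1e-9))
  sev_true <- vapply(co, function(x) as.character(x$severity), character(1))
  per_case <- rep[rep$map_kind == "cbf", ]
  for (cls in unique(sev_true)) {
    expect_equal(sum(per_case$severity == cls), sum(sev_true == cls))
  }
  smry <- summarize_eval(rep)
  expect_true(all(c("severity", "ratio") %in% smry$stratum_by))

  bad <- pred; names(bad)[1] <- "nonexistent"
  expect_error(evaluate_cohort(bad, co), "pair")
})
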