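# Reader-study statistics: blinded trial construction, agreement, kappa
# and the kappa power simulation.

test_that("build_trials separates arms, shuffles, and unblinds exactly", {
  ids <- sprintf("case%02d", 1:20)
  tr <- build_trials(ids, seed = 3)
  expect_equal(nrow(tr$trial1), 20)
  expect_equal(nrow(tr$trial2), 20)
  expect_setequal(tr$trial1$case_id, ids)
  expect_setequal(tr$trial2$case_id, ids)
  merged <- merge(tr$trial1, tr$trial2, by = "case_id")
  expect_true(all(merged$arm.x != merged$arm.y))
  expect_identical(build_trials(ids, seed = 3), tr)
  # unblinding key recovers each roster entry
  k1 <- tr$key[tr$key$trial == "trial1", ]
  expect_equal(k1[match(tr$trial1$pseudo_id, k1$pseudo_id), "case_id"],
               tr$trial1$case_id)
  df <- data.frame(case_id = c("a", "a", "b"),
                   arm = c("real", "synthetic", "real"))
  expect_error(build_trials(df, 1), "missing an arm")
})

test_that("contingency tables keep empty categories and reject unknown codes", {
  cats <- c("Acceptable", "Indeterminate", "Unacceptable")
  a <- rep("Acceptable", 5)
  b <- c(rep("Acceptable", 4), "Indeterminate")
  m <- contingency(a, b, cats)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m[1, 1], 4)
  expect_equal(m[1, 2], 1)
  expect_equal(sum(m), 5)
  expect_error(contingency(c(a, "Weird"), c(b, "Acceptable"), cats),
               "codebook")
  expect_error(contingency(a, b[1:3], cats), "paired")
})

test_that("percent agreement matches the Wilson interval", {
  m <- diag(c(70, 70))
  pa <- percent_agreement(m)
  expect_equal(pa$estimate, 1)
  expect_equal(pa$ci[2], 1)
  # 133 agreements of 140: the point estimate is 95.0%
  m2 <- matrix(c(100, 3, 4, 33), 2)
  pa2 <- percent_agreement(m2)
  expect_equal(pa2$estimate, 0.95)
  ref <- prop.test(133, 140, correct = FALSE)$conf.int
  expect_equal(pa2$ci, as.numeric(ref), tolerance = 1e-9)
  expect_equal(percent_agreement(matrix(c(0, 5, 5, 0), 2))$estimate, 0)
  expect_error(percent_agreement(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa reproduces the hand cases and the degenerate convention", {
  expect_equal(cohens_kappa(diag(c(30, 40, 30)))$kappa, 1)
  # one arm constant, the other varying: chance agreement equals observed
  m_const <- matrix(c(90, 0, 10, 0), 2, byrow = TRUE)
  expect_equal(cohens_kappa(m_const)$kappa, 0)
  # both arms constant (the degenerate pattern): kappa defined as 0
  m_deg <- matrix(c(140, 0, 0, 0), 2)
  kd <- cohens_kappa(m_deg)
  expect_equal(kd$kappa, 0)
  expect_equal(kd$ci, c(0, 0))
  m <- matrix(c(40, 10, 10, 40), 2)
  expect_equal(cohens_kappa(m)$kappa, 0.6, tolerance = 1e-12)
})

test_that("kappa agrees with an independent implementation and is relabeling-invariant", {
  skip_if_not_installed("e1071")
  set.seed(50)
  m <- matrix(rpois(16, 20), 4)
  expect_equal(cohens_kappa(m)$kappa,
               e1071::classAgreement(m)$kappa, tolerance = 1e-10)
  perm <- c(3, 1, 4, 2)
  expect_equal(cohens_kappa(m[perm, perm])$kappa, cohens_kappa(m)$kappa,
               tolerance = 1e-12)
})

test_that("bootstrap and asymptotic kappa intervals agree on large tables", {
  p <- c(0.5, 0.3, 0.2)
  P <- 0.6 * outer(p, p) + 0.4 * diag(p)
  set.seed(51)
  m <- matrix(rmultinom(1, 800, as.vector(P)), 3)
  ka <- cohens_kappa(m, ci = "asymptotic")
  kb <- cohens_kappa(m, ci = "bootstrap", B = 1000, seed = 4)
  expect_lt(max(abs(ka$ci - kb$ci)), 0.05)
})

test_that("kappa power is calibrated at the null and monotone in n", {
  p3 <- rep(1 / 3, 3)
  p0 <- kappa_power(0, p3, n = 140, alpha = 0.05, reps = 1500, seed = 5)
  expect_lt(abs(p0 - 0.05), 0.02)
  pow <- vapply(c(50, 140, 500), function(n)
    kappa_power(0.35, p3, n, reps = 1000, seed = 6), numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_error(kappa_power(0.35, p3, 140, reps = 10), "1000")
  expect_error(kappa_power(0.2, c(0.5, 0.6), 100), "sum to 1")
  expect_error(kappa_power(-0.9, c(0.95, 0.05), 100), "incompatible")
})
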