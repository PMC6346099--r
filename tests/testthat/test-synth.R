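test_that("cohort generator produces the requested case/control split with valid structure", {
  coh <- generate_cohort(n = 512, n_cases = 217, seed = 1)
  expect_equal(sum(coh$future_case), 217)
  expect_equal(sum(!coh$future_case), 295)
  expect_silent(validate_cohort(coh))
  # batch sizes: at least two per level
  expect_true(all(table(coh$batch) >= 2))
  # follow-up within the stated range, cases only
  tt <- coh$time_to_diagnosis[coh$future_case]
  expect_true(all(tt >= 2 & tt <= 17))
  expect_true(all(is.na(coh$time_to_diagnosis[!coh$future_case])))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(100, 40, seed = 9)
  b <- generate_cohort(100, 40, seed = 9)
  expect_identical(a, b)
  c <- generate_cohort(100, 40, seed = 10)
  expect_false(identical(a, c))
})

test_that("cohort generator rejects invalid parameters", {
  expect_error(generate_cohort(10, 11), "n_cases")
  expect_error(cohort_config(pcb_sdlog = c(0.5, -1, 0.5, 0.5, 0.5, 0.5)), "positive")
  expect_error(cohort_config(wbc_concentration = rep(0, 6)), "positive")
  expect_error(cohort_config(pcb_corr = 1.2), "pcb_corr")
})

test_that("with no sex shift the per-congener sex t-tests are null-uniform", {
  cfg <- cohort_config(sex_shift_sd = 0)
  pmat <- vapply(seq_len(200), function(s) {
    coh <- generate_cohort(100, 40, config = cfg, seed = 1000 + s)
    exposure_sex_ttest(coh)$p
  }, numeric(6))
  for (i in 1:6) {
    ks <- suppressWarnings(stats::ks.test(pmat[i, ], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("wbc proportions are simplex rows with the Dirichlet mean", {
  w <- generate_wbc_proportions(10000, rep(10, 6), seed = 3)
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  expect_true(all(w >= 0))
  expect_true(all(abs(colMeans(w) - 1 / 6) < 0.01))
  # degenerate concentration pins the mass on one type
  wd <- generate_wbc_proportions(50, c(1e6, rep(1e-6, 5)), seed = 4)
  expect_true(all(wd[, 1] > 1 - 1e-3))
  expect_error(generate_wbc_proportions(5, c(1, -1, 1, 1, 1, 1)), "> 0")
})

test_that("expression generation is deterministic and shape-correct", {
  coh <- small_cohort()
  tr <- simulation_truth(25)
  a <- generate_expression(coh, tr, seed = 5)
  b <- generate_expression(coh, tr, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a), c(25, nrow(coh)))
  expect_identical(colnames(a), coh$subject_id)
  expect_error(generate_expression(coh, tr, n_transcripts = 10), "match")
})

test_that("a planted interaction is recovered unbiasedly by the correctly-specified OLS refit", {
  # no batch variance: the true model is plain OLS in the product term
  covered <- vapply(seq_len(100), function(s) {
    coh <- generate_cohort(500, 200, seed = 3000 + s)
    tr <- simulation_truth(1, sigma2_u = 0, sigma2_e = 1)
    tr <- plant_interaction(tr, 1, "156", "B", 0.5)
    y <- generate_expression(coh, tr, seed = 4000 + s)[1, ]
    x <- transform_exposure(coh$pcb_156)
    w <- coh$wbc_B
    fit <- stats::lm(y ~ x + w + I(x * w))
    ci <- stats::confint(fit)["I(x * w)", ]
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 93)
})

test_that("planted effects respect the sex-specific mask", {
  coh <- small_cohort(n = 300, n_cases = 100)
  tr <- simulation_truth(2, sigma2_u = 0, sigma2_e = 0.01)
  tr <- plant_interaction(tr, 1, "153", "CD4T", 3, sex = "F")
  y <- generate_expression(coh, tr, seed = 6)
  x <- transform_exposure(coh$pcb_153) * coh$wbc_CD4T
  rF <- abs(stats::cor(y[1, coh$sex == "F"], x[coh$sex == "F"]))
  rM <- abs(stats::cor(y[1, coh$sex == "M"], x[coh$sex == "M"]))
  expect_gt(rF, 0.8)
  expect_lt(rM, 0.3)
})

test_that("grid of planted interaction effects is recovered without bias", {
  for (b0 in c(0, 0.2, 0.5, 1.0)) {
    est <- vapply(seq_len(25), function(s) {
      coh <- generate_cohort(300, 120, seed = 5000 + s)
      tr <- simulation_truth(1, sigma2_u = 0, sigma2_e = 1)
      tr <- plant_interaction(tr, 1, "170", "Mono", b0)
      y <- generate_expression(coh, tr, seed = 6000 + s)[1, ]
      x <- transform_exposure(coh$pcb_170)
      w <- coh$wbc_Mono
      stats::coef(stats::lm(y ~ x + w + I(x * w)))["I(x * w)"]
    }, numeric(1))
    # Monte-Carlo error band: 4 * se of the mean estimate
    expect_lt(abs(mean(est) - b0), 4 * stats::sd(est) / sqrt(length(est)))
  }
})

test_that("methylation generator mixes the reference linearly and clips", {
  ref <- small_reference(20)
  # vertex: pure cell type j reproduces reference column j
  f <- matrix(0, 1, 6); f[1, 2] <- 1
  m <- generate_methylation(f, ref, noise_sd = 0)
  expect_equal(unname(m[, 1]), unname(ref[, 2]))
  # linearity: 50/50 mixture is the mean of two columns
  f2 <- matrix(c(0.5, 0.5, 0, 0, 0, 0), 1)
  m2 <- generate_methylation(f2, ref, noise_sd = 0)
  expect_equal(unname(m2[, 1]), unname((ref[, 1] + ref[, 2]) / 2))
  # clipping holds for any noise level
  f3 <- generate_wbc_proportions(10, rep(5, 6), seed = 1)
  m3 <- generate_methylation(f3, ref, noise_sd = 5, seed = 2)
  expect_true(all(m3 >= 0 & m3 <= 1))
  expect_error(generate_methylation(matrix(c(0.9, 0.4, 0, 0, 0, 0), 1), ref, 0),
               "simplex")
})
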