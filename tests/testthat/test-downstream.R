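test_that("identical sex distributions give t = 0, p = 1", {
  coh <- small_cohort(n = 60, n_cases = 20)
  # force males to mirror females exactly on the exposures
  nF <- sum(coh$sex == "F")
  coh$sex <- factor(rep(c("F", "M"), length.out = nrow(coh)), levels = c("F", "M"))
  half <- coh$sex == "F"
  for (cn in paste0("pcb_", PCB_CONGENERS)) coh[[cn]][!half] <- coh[[cn]][half]
  tt <- exposure_sex_ttest(coh)
  expect_equal(tt$t, rep(0, 6), tolerance = 1e-12)
  expect_equal(tt$p, rep(1, 6), tolerance = 1e-12)
})

test_that("the default generator yields the female-shifted congener pattern", {
  coh <- generate_cohort(512, 217, seed = 61)
  tt <- exposure_sex_ttest(coh)
  shifted <- tt$congener %in% c("118", "156", "170", "180")
  expect_true(all(tt$p[shifted] < 0.05))
  expect_true(all(tt$mean_F[shifted] > tt$mean_M[shifted]))
  coh1 <- coh; coh1$sex <- factor(rep("F", nrow(coh)), levels = c("F", "M"))
  expect_error(exposure_sex_ttest(coh1), "both sexes")
})

test_that("gene-list overlap arithmetic", {
  hits <- paste0("g", 1:50)
  known <- c(paste0("g", 1:5), paste0("k", 1:20))
  ov <- gene_list_overlap(hits, known)
  expect_equal(ov$n_overlap, 5)
  expect_equal(ov$fraction_of_hits, 0.1)
  expect_setequal(ov$novel, paste0("g", 6:50))
  same <- gene_list_overlap(hits, hits)
  expect_equal(same$fraction_of_hits, 1)
  expect_length(same$novel, 0)
  disj <- gene_list_overlap(hits, paste0("z", 1:3))
  expect_equal(disj$fraction_of_hits, 0)
  expect_setequal(disj$novel, hits)
  expect_error(gene_list_overlap(character(0), known), "empty")
})

test_that("hypergeometric ORA equals exhaustive enumeration on small universes", {
  bg <- paste0("g", 1:20)
  pw <- paste0("g", 1:5)
  hits <- c("g1", "g2", "g3", "g4", "g11")   # overlap 4
  res <- ora_hypergeometric(hits, list(pw = pw), bg)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, hyper_tail_oracle(bg, pw, length(hits), 4),
               tolerance = 1e-12)
  # a second configuration with |background| = 18
  bg2 <- paste0("h", 1:18)
  pw2 <- paste0("h", c(2, 5, 9, 13))
  hits2 <- paste0("h", c(2, 5, 7, 11))
  res2 <- ora_hypergeometric(hits2, list(pw = pw2), bg2)
  expect_equal(res2$p, hyper_tail_oracle(bg2, pw2, 4, res2$overlap),
               tolerance = 1e-12)
})

test_that("ORA saturates at p = 1 and its q-values reproduce bh_fdr", {
  bg <- paste0("g", 1:30)
  hits <- paste0("g", 1:6)
  res <- ora_hypergeometric(hits, list(all = bg), bg)
  expect_equal(res$overlap, 6)
  expect_equal(res$p, 1)
  many <- ora_hypergeometric(hits, list(a = bg[1:10], b = bg[5:20], c = bg[25:30]), bg)
  expect_equal(many$q, bh_fdr(many$p)$q_values)
  expect_error(ora_hypergeometric(c(hits, "zzz"), list(a = bg[1:4]), bg), "subset")
})

test_that("differential expression matches a hand-computed Welch statistic", {
  g1 <- matrix(c(1, 2, 3, 10, 11, 12), 2, 3, byrow = TRUE)
  g2 <- matrix(c(5, 6, 7, 7, 10, 12, 9, 14), 2, 4, byrow = TRUE)
  x <- cbind(g1, g2)
  rownames(x) <- c("gA", "gB")
  labels <- rep(c("a", "b"), c(3, 4))
  res <- diff_expr_signature(x, labels, fc_cut = 1.01, q_cut = 0.99)
  # hand Welch for gA: means 2 vs 6.25, vars 1 vs 0.9166667
  se <- sqrt(1 / 3 + 0.9166667 / 4)
  expect_equal(res$table$t[1], (2 - 6.25) / se, tolerance = 1e-6)
  expect_equal(res$table$log2_fc[1], 2 - 6.25)
  expect_equal(res$table$log2_fc[2], 11 - 11.25)
  # identical group means: nothing significant
  xx <- matrix(rep(c(1, 2, 3, 1, 2, 3, 1.01, 2.01), 3), 3, 8, byrow = TRUE)
  r0 <- diff_expr_signature(xx + matrix(rnorm(24, sd = 1e-3), 3), rep(c("a", "b"), 4))
  expect_false(any(r0$table$significant))
})

test_that("signature tails are disjoint subsets of the significant set", {
  set.seed(62)
  n <- 40
  x <- matrix(rnorm(200 * n), 200, n)
  rownames(x) <- paste0("g", 1:200)
  shift <- rep(0, 200); shift[1:20] <- 3; shift[181:200] <- -3
  x[, 1:(n / 2)] <- x[, 1:(n / 2)] + shift
  res <- diff_expr_signature(x, rep(c("case", "ctrl"), each = n / 2),
                             fc_cut = 1.5, q_cut = 0.05, tail_frac = 0.05)
  sig <- res$table$gene[res$table$significant]
  expect_length(intersect(res$up, res$down), 0)
  expect_true(all(res$up %in% sig))
  expect_true(all(res$down %in% sig))
  expect_true(all(grepl("^g(1?[0-9]|20)$", res$up)))   # up-tail from the planted block
})

test_that("time-to-diagnosis correlation matches the closed form and its invariances", {
  tt <- c(2, 4, 5, 9, 12)
  x <- rbind(lin = 1.5 * tt - 2,
             arb = c(3, 1, 4, 1, 5))
  res <- ttd_correlation(x, tt)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  # closed-form Pearson on the 5-point fixture
  num <- sum((x[2, ] - mean(x[2, ])) * (tt - mean(tt)))
  den <- sqrt(sum((x[2, ] - mean(x[2, ]))^2) * sum((tt - mean(tt))^2))
  expect_equal(res$r[2], num / den, tolerance = 1e-12)
  # affine transforms preserve the sign and magnitude
  res2 <- ttd_correlation(x * 3 + 7, tt * 2 + 1)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  # constant gene yields NA
  res3 <- ttd_correlation(rbind(const = rep(1, 5)), tt)
  expect_true(is.na(res3$r[1]))
  expect_error(ttd_correlation(x[, 1:2], tt[1:2]), "at least 3")
})

test_that("batch correction removes the planted batch offsets", {
  coh <- generate_cohort(200, 80, seed = 63)
  tr <- simulation_truth(20, sigma2_u = 2, sigma2_e = 0.5)
  y <- generate_expression(coh, tr, seed = 64)
  yc <- batch_correct(y, coh)
  b <- coh$batch
  # between-batch variance of batch means should shrink markedly
  raw_between <- mean(apply(y, 1, function(r) stats::var(tapply(r, b, mean))))
  cor_between <- mean(apply(yc, 1, function(r) stats::var(tapply(r, b, mean))))
  expect_lt(cor_between, raw_between / 3)
})

test_that("stratified count table has the published layout and respects min_n", {
  coh <- generate_cohort(260, 110, seed = 65)
  tr <- simulation_truth(60)
  y <- generate_expression(coh, tr, seed = 66)
  tab <- stratified_scan_counts(y, coh, strata_plan = "sex_case",
                                pcbs = c("156", "170"), wbcs = c("B", "Mono"),
                                min_n = 30)
  expect_s3_class(tab, "count_table")
  expect_equal(nrow(tab), 2 * 2 * 2)   # sex x pcb x cell type
  expect_named(tab, c("sex", "cell_type", "pcb", "controls", "overlap",
                      "future_cases"))
  ok <- !is.na(tab$overlap)
  expect_true(all(tab$overlap[ok] <= pmin(tab$controls[ok], tab$future_cases[ok])))
  # a null-configured simulation yields (almost) no discoveries
  expect_true(mean(c(tab$controls, tab$future_cases) == 0, na.rm = TRUE) >= 0.9)
  # strata below min_n become NA cells
  tab2 <- stratified_scan_counts(y, coh, strata_plan = "sex_case",
                                 pcbs = "156", wbcs = "B", min_n = 1000)
  expect_true(all(is.na(tab2$controls)))
  # sex-only plan with main-effect scans
  tab3 <- stratified_scan_counts(y, coh, strata_plan = "sex",
                                 pcbs = "156", wbcs = NULL, min_n = 30)
  expect_equal(nrow(tab3), 2)
  expect_named(tab3, c("stratum", "cell_type", "pcb", "n_significant"))
})
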