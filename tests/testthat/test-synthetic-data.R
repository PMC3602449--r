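test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  panel <- simulate_genotypes(10000, 0.5, seed = 51)
  het <- mean(panel$calls == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))

  panel <- simulate_genotypes(50000, 0.2, seed = 52)
  maf <- snp_maf(panel)
  expect_lt(abs(maf - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * 50000)))

  # exact-test P-values across replicates behave like a valid test
  pvals <- vapply(1:200, function(s) {
    pp <- simulate_genotypes(300, 0.3, seed = 1000 + s)
    cnt <- genotype_counts(pp)
    hwe_exact_test(cnt$n_hom_minor, cnt$n_het, cnt$n_hom_major)
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.08)   # level at most nominal + MC noise
  expect_gt(mean(pvals), 0.4)             # not degenerate toward 0
})

test_that("invalid frequencies and indices are rejected", {
  expect_error(simulate_genotypes(10, 0), "frequencies")
  expect_error(simulate_genotypes(10, 0.6), "frequencies")
  expect_error(sim_config(n_snps = 5,
                          snp_effects = data.frame(snp = 9, effect = -1)),
               "out-of-range")
  expect_error(sim_config(visit_months = c(0, 3, 3)), "increasing")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("noise-free cohorts reproduce the generative slopes exactly", {
  cfg <- sim_config(n_subjects = 30, n_snps = 10, within_subject_sd = 0,
                    between_subject_slope_sd = 0, seed = 53)
  ch <- simulate_cohort(cfg)
  sl <- estimate_all_slopes(ch$phenotype)
  expect_equal(sl$es, rep(cfg$slope_intercept, nrow(sl)), tolerance = 1e-10)

  # planted dominant effect: carrier-vs-noncarrier contrast is exact
  cfg <- sim_config(n_subjects = 60, n_snps = 10,
                    snp_effects = data.frame(snp = 4, effect = -15),
                    within_subject_sd = 0, between_subject_slope_sd = 0,
                    seed = 54)
  ch <- simulate_cohort(cfg)
  sl <- estimate_all_slopes(ch$phenotype)
  carrier <- ch$panel$calls[match(sl$subject, ch$panel$subjects), 4] >= 1
  expect_equal(mean(sl$es[carrier]) - mean(sl$es[!carrier]), -15,
               tolerance = 1e-10)
})

test_that("pipeline slopes track truth closely at modest noise", {
  cfg <- sim_config(n_subjects = 301, n_snps = 20, within_subject_sd = 40,
                    dropout_probs = c(1, 1, 1, 1), seed = 55)
  ch <- simulate_cohort(cfg)
  sl <- estimate_all_slopes(ch$phenotype)
  truth <- ch$truth$subjects$true_slope[match(sl$subject,
                                              ch$truth$subjects$subject)]
  expect_gt(cor(sl$es, truth), 0.9)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- simulate_cohort(sim_config(n_subjects = 40, n_snps = 30, seed = 56))
  b <- simulate_cohort(sim_config(n_subjects = 40, n_snps = 30, seed = 56))
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$covariates$data, b$covariates$data)
  expect_identical(a$truth, b$truth)
})

test_that("dropout retention reproduces the follow-up pattern", {
  ch <- simulate_cohort(sim_config(n_subjects = 4000, n_snps = 2, seed = 57))
  nv <- ch$truth$subjects$n_visits
  # everyone has baseline + 3 months; 12- and 18-month retention as set
  expect_true(all(nv >= 2))
  p12 <- mean(nv >= 3)
  expect_lt(abs(p12 - 239 / 301), 3 * sqrt(0.8 * 0.2 / 4000))
  p18_given_12 <- mean(nv[nv >= 3] == 4)
  expect_lt(abs(p18_given_12 - 197 / 239), 3 * sqrt(0.8 * 0.2 / 3000))
})

test_that("QC fixture violation counts are honoured exactly", {
  # nothing planted, nothing removed
  fx <- make_qc_fixture(n_subjects = 60, n_snps = 200, seed = 58)
  s1 <- snp_filter(fx)
  expect_identical(sum(s1$report$steps$removed), 0L)
  s2 <- sample_filter(s1$panel)
  expect_identical(sum(s2$report$steps$removed), 0L)

  # arbitrary feasible counts: survivor arithmetic is exact
  fx <- make_qc_fixture(n_subjects = 90, n_snps = 400, n_nonautosomal = 17,
                        n_low_callrate = 23, n_low_maf = 41, n_hwe_fail = 9,
                        seed = 59)
  out <- snp_filter(fx)
  expect_identical(out$report$steps$removed, c(17L, 23L, 41L, 9L))
  expect_identical(out$report$n_survivors, 400L - 90L)

  fx <- make_qc_fixture(n_subjects = 150, n_snps = 500,
                        n_subject_low_callrate = 2, n_related = 3,
                        n_outliers = 2, seed = 60)
  out <- sample_filter(fx)
  expect_identical(out$report$steps$removed, c(2L, 3L, 2L))
  expect_identical(out$report$n_survivors, 143L)

  expect_error(make_qc_fixture(10, 50, n_low_maf = 60), "infeasible")
  expect_error(make_qc_fixture(5, 50, n_related = 4), "infeasible")
  expect_error(make_qc_fixture(30, 50, n_outliers = 1), "infeasible")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(n_subjects = 33, n_snps = 7,
                    snp_effects = data.frame(snp = 2, effect = -9),
                    seed = 63)
  d <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d)
  back <- read_sim_config(file.path(d, "config.yaml"))
  expect_equal(back$n_subjects, cfg$n_subjects)
  expect_equal(back$snp_effects, cfg$snp_effects)
  expect_equal(back$dropout_probs, cfg$dropout_probs, tolerance = 1e-9)
  # identical configs regenerate identical cohorts
  expect_identical(simulate_cohort(back)$phenotype,
                   simulate_cohort(cfg)$phenotype)
})

test_that("duplicated SNPs copy calls and respect the flip probability", {
  panel <- simulate_genotypes(200, rep(0.3, 3), seed = 61)
  dup <- duplicate_snp(panel, "snp00002", "snp_copy", flip_prob = 0)
  expect_identical(unname(dup$calls[, 4]), unname(panel$calls[, 2]))
  noisy <- duplicate_snp(panel, "snp00002", "snp_noisy", flip_prob = 0.2,
                         seed = 62)
  frac_changed <- mean(noisy$calls[, 4] != panel$calls[, 2])
  expect_gt(frac_changed, 0.05)
  expect_lt(frac_changed, 0.35)
})
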