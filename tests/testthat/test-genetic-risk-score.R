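test_that("risk sides follow the sign of the dominant beta", {
  res <- data.frame(snp_id = c("rs1910047", "rs32588"),
                    beta = c(-15.17, 17.21))
  coding <- derive_risk_coding(res)
  expect_identical(coding$risk_side, c("carrier", "noncarrier"))
  expect_error(derive_risk_coding(data.frame(snp_id = "x", beta = 0)),
               "undefined")
  expect_error(derive_risk_coding(data.frame(snp_id = "x", beta = NA_real_)),
               "finite")
})

test_that("scores equal a brute-force per-subject recount", {
  panel <- simulate_genotypes(80, runif(10, 0.1, 0.5), seed = 141)
  panel$calls[cbind(sample(80, 15, TRUE), sample(10, 15, TRUE))] <-
    NA_integer_
  coding <- structure(data.frame(
    snp_id = panel$snps$snp_id,
    risk_side = sample(c("carrier", "noncarrier"), 10, TRUE),
    stringsAsFactors = FALSE), class = c("risk_coding", "data.frame"))
  scores <- compute_grs(panel, coding)
  for (i in sample(80, 20)) {
    cnt <- 0
    for (j in 1:10) {
      g <- panel$calls[i, j]
      if (is.na(g)) next
      carrier <- g >= 1  # allele_b is minor in simulated panels
      if ((carrier && coding$risk_side[j] == "carrier") ||
          (!carrier && coding$risk_side[j] == "noncarrier"))
        cnt <- cnt + 1
    }
    expect_identical(scores$grs[i], as.integer(cnt))
  }
  expect_identical(scores$n_missing,
                   as.integer(rowSums(is.na(panel$calls))))
})

test_that("scores hit the extremes and are invariant to SNP order", {
  calls <- rbind(rep(1L, 6), rep(0L, 6),
                 matrix(rbinom(6 * 30, 2, 0.4), 30, 6))
  panel <- toy_panel(calls)
  coding <- structure(data.frame(snp_id = panel$snps$snp_id,
                                 risk_side = "carrier",
                                 stringsAsFactors = FALSE),
                      class = c("risk_coding", "data.frame"))
  scores <- compute_grs(panel, coding)
  expect_identical(scores$grs[1], 6L)   # carrier of all risk genotypes
  expect_identical(scores$grs[2], 0L)   # carrier of none
  shuffled <- coding[sample(nrow(coding)), ]
  class(shuffled) <- class(coding)
  expect_identical(compute_grs(panel, shuffled)$grs, scores$grs)
})

test_that("flipping a SNP's risk side complements its contribution", {
  panel <- simulate_genotypes(60, runif(5, 0.2, 0.5), seed = 142)
  coding <- derive_risk_coding(data.frame(snp_id = panel$snps$snp_id,
                                          beta = rep(-1, 5)))
  base <- compute_grs(panel, coding)
  flipped <- coding
  flipped$risk_side[3] <- "noncarrier"
  flip_scores <- compute_grs(panel, flipped)
  carrier3 <- panel$calls[, 3] >= 1
  delta <- ifelse(is.na(carrier3), 0, ifelse(carrier3, -1L, 1L))
  expect_identical(flip_scores$grs, as.integer(base$grs + delta))
})

test_that("the trend beta recovers a planted per-risk-genotype effect exactly", {
  set.seed(143)
  n <- 120
  grs <- sample(0:10, n, TRUE)
  Z <- random_covariates(n)
  y <- -2 - 3 * grs + 0.1 * (Z[, "age"] - mean(Z[, "age"]))
  fit <- grs_trend(y, grs, Z)
  expect_equal(fit$beta, -3, tolerance = 1e-9)
  yn <- y + rnorm(n, 0, 6)
  oracle <- ols_oracle(yn, cbind(1, grs, Z))
  fitn <- grs_trend(yn, grs, Z)
  expect_equal(fitn$beta, oracle$beta[2], tolerance = 1e-10)
  expect_equal(fitn$se, oracle$se[2], tolerance = 1e-10)
  expect_equal(fitn$p_trend, oracle$p[2], tolerance = 1e-10)
  expect_error(grs_trend(y, rep(3, n), Z), "constant")
})

test_that("trend P-values are calibrated under the null", {
  pvals <- vapply(1:60, function(s) {
    set.seed(300 + s)
    n <- 150
    grs <- rbinom(n, 10, 0.4)
    Z <- random_covariates(n)
    y <- rnorm(n, -6, 10)
    grs_trend(y, grs, Z)$p_trend
  }, numeric(1))
  expect_gt(mean(pvals <= 0.5), 0.35)
  expect_lt(mean(pvals <= 0.5), 0.65)
  expect_lte(mean(pvals <= 0.05), 0.15)
})

test_that("an end-to-end cohort-scale GRS is overwhelmingly significant", {
  # ten dominant risk SNPs with table-scale effects in a 301-subject cohort
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_subjects = 301, n_snps = 10,
                      snp_effects = data.frame(snp = 1:10,
                                               effect = c(-15, -12, 17, 15,
                                                          10, -10, 10, 11,
                                                          -12, -10)),
                      seed = 400 + s)
    ch <- simulate_cohort(cfg)
    sl <- estimate_all_slopes(ch$phenotype)
    sc <- assoc_scan(ch$panel, sl, ch$covariates, "dominant")
    coding <- derive_risk_coding(sc)
    scores <- compute_grs(ch$panel, coding)
    Z <- build_covariate_matrix(ch$covariates)
    idx <- match(sl$subject, scores$subject)
    fit <- grs_trend(sl$es, scores[idx, ], Z[sl$subject, ])
    expect_lt(fit$beta, 0)  # more risk genotypes, faster decline
    if (fit$p_trend < 1e-10) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("stratified trends collapse to the pooled fit for one stratum", {
  set.seed(144)
  n <- 100
  grs <- rbinom(n, 8, 0.5)
  Z <- random_covariates(n)[, c("height", "fev1_baseline")]
  y <- -3 - 2 * grs + rnorm(n, 0, 6)
  pooled <- grs_trend(y, grs, Z)
  strat <- grs_stratified(y, grs, Z, strata = rep("all", n))
  expect_equal(strat$per_stratum$beta, pooled$beta, tolerance = 1e-10)
  expect_true(is.na(strat$interaction_p))
})

test_that("identical stratum trends give a null interaction; distinct ones are found", {
  set.seed(145)
  n <- 120
  grs <- rbinom(n, 8, 0.5)
  st <- factor(sample(c("young", "old"), n, TRUE), c("young", "old"))
  Z <- random_covariates(n)[, c("height", "fev1_baseline")]
  y0 <- -3 - 2 * grs + 1 * (st == "old")
  same <- grs_stratified(y0, grs, Z, st)
  expect_gt(same$interaction_p, 1 - 1e-6)
  expect_equal(same$interaction_betas, 0, tolerance = 1e-8)

  found <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 300
    grs <- rbinom(n, 8, 0.5)
    st <- factor(sample(c("young", "old"), n, TRUE), c("young", "old"))
    Z <- random_covariates(n)[, c("height", "fev1_baseline")]
    y <- -3 + ifelse(st == "young", -5, -1) * grs + rnorm(n, 0, 8)
    fit <- grs_stratified(y, grs, Z, st)
    if (fit$interaction_p < 0.05) found <- found + 1
  }
  expect_gte(found, 16)  # 80% detection at this effect contrast
})

test_that("thin strata are flagged and subjects with many missing calls dropped", {
  set.seed(146)
  n <- 60
  grs <- rbinom(n, 8, 0.5)
  Z <- random_covariates(n)[, c("height", "fev1_baseline")]
  y <- -3 - 2 * grs + rnorm(n, 0, 5)
  st <- factor(c(rep("big", n - 2), "tiny", "tiny"))
  fit <- grs_stratified(y, grs, Z, st)
  expect_true(fit$per_stratum$flagged[fit$per_stratum$stratum == "tiny"])

  scores <- data.frame(subject = paste0("s", 1:n), grs = grs,
                       n_missing = c(rep(0L, n - 4), rep(5L, 4)))
  fit2 <- grs_trend(y, scores, Z, max_missing_frac = 0.2, n_coded = 8)
  expect_equal(fit2$n, n - 4)
})
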