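# deterministic two-SNP design with optional synergy in the (1,1) cell
two_snp_data <- function(n = 120, synergy = 0, noise_sd = 0, seed = 121,
                         beta_a = -8, beta_b = -6) {
  set.seed(seed)
  a <- rbinom(n, 1, 0.4)
  b <- rbinom(n, 1, 0.35)
  Z <- random_covariates(n)
  y <- -4 + beta_a * a + beta_b * b + synergy * a * b +
    0.05 * (Z[, "age"] - mean(Z[, "age"]))
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  list(y = y, a = a, b = b, Z = Z)
}

test_that("purely additive generative effects give a zero product coefficient", {
  d <- two_snp_data(synergy = 0, noise_sd = 0)
  fit <- fit_gene_gene(d$y, d$a, d$b, d$Z)
  expect_equal(fit$interaction_beta, 0, tolerance = 1e-9)
})

test_that("planted synergy appears exactly in the joint cell and the product term", {
  d <- two_snp_data(synergy = -20, noise_sd = 0)
  fit <- fit_gene_gene(d$y, d$a, d$b, d$Z, labels = c("rsA", "rsB"))
  expect_equal(fit$interaction_beta, -20, tolerance = 1e-8)
  cells <- fit$cells
  b01 <- cells$beta[cells$level_a == 0 & cells$level_b == 1]
  b10 <- cells$beta[cells$level_a == 1 & cells$level_b == 0]
  b11 <- cells$beta[cells$level_a == 1 & cells$level_b == 1]
  expect_equal(b10, -8, tolerance = 1e-8)
  expect_equal(b01, -6, tolerance = 1e-8)
  expect_equal(b11, -8 + -6 + -20, tolerance = 1e-8)
  # reference cell carries no beta and cell sizes partition the sample
  expect_true(is.na(cells$beta[cells$level_a == 0 & cells$level_b == 0]))
  expect_identical(sum(cells$n), fit$n)
})

test_that("product and joint-cell parameterizations are linear re-codings", {
  set.seed(122)
  for (rep in 1:10) {
    d <- two_snp_data(synergy = rnorm(1, 0, 10), noise_sd = 12,
                      seed = 123 + rep)
    fit <- fit_gene_gene(d$y, d$a, d$b, d$Z)
    oracle <- ols_oracle(d$y, cbind(1, d$Z, d$a, d$b, d$a * d$b))
    k <- ncol(d$Z)
    expect_equal(fit$interaction_beta, oracle$beta[k + 4], tolerance = 1e-8)
    expect_equal(fit$interaction_p, oracle$p[k + 4], tolerance = 1e-8)
    # joint-cell betas are sums of the product-model terms
    cells <- fit$cells
    b11 <- cells$beta[cells$level_a == 1 & cells$level_b == 1]
    expect_equal(b11, sum(oracle$beta[k + 2:4]), tolerance = 1e-7)
  }
})

test_that("an empty cell suppresses joint-cell betas but keeps the product P", {
  d <- two_snp_data(noise_sd = 5)
  # force the (1,1) cell empty
  d$b[d$a == 1] <- 0
  fit <- fit_gene_gene(d$y, d$a, d$b, d$Z)
  expect_true(all(is.na(fit$cells$beta)))
  # product term is collinear here, so the P may be NA; the call must not fail
  expect_true(is.list(fit))
  # an empty off-diagonal cell leaves only 3 populated cells for 4 genotype
  # parameters: the product design goes rank-deficient, flagged not fatal
  d2 <- two_snp_data(noise_sd = 5, seed = 124)
  keep <- !(d2$a == 0 & d2$b == 1)
  fit2 <- fit_gene_gene(d2$y[keep], d2$a[keep], d2$b[keep],
                        d2$Z[keep, , drop = FALSE])
  expect_true(is.na(fit2$interaction_p))
})

test_that("a genotype effect constant across environment gives a zero F statistic", {
  set.seed(125)
  n <- 150
  g <- rbinom(n, 1, 0.4)
  env <- factor(sample(c("<18", "18-25", ">=25"), n, TRUE),
                levels = c("<18", "18-25", ">=25"))
  Z <- random_covariates(n)[, c("height", "fev1_baseline", "log_endotoxin")]
  y <- -3 - 9 * g + 2 * (env == "18-25") - 4 * (env == ">=25")
  fit <- fit_gene_environment(y, g, env, Z)
  expect_equal(fit$f_stat, 0, tolerance = 1e-9)
  expect_equal(fit$interaction_p, 1, tolerance = 1e-6)
})

test_that("for a 2-level environment the F-test equals the squared-t product test", {
  set.seed(126)
  n <- 140
  g <- rbinom(n, 1, 0.4)
  env01 <- rbinom(n, 1, 0.5)
  Z <- random_covariates(n)[, c("height", "age", "fev1_baseline")]
  y <- -4 - 6 * g - 3 * env01 - 8 * g * env01 + rnorm(n, 0, 10)
  fe <- fit_gene_environment(y, g, factor(env01, levels = 0:1), Z)
  oracle <- ols_oracle(y, cbind(1, Z, g, env01, g * env01))
  tstat <- (oracle$beta / oracle$se)[ncol(Z) + 4]
  expect_equal(fe$f_stat, tstat^2, tolerance = 1e-8)
  expect_equal(fe$interaction_p, oracle$p[ncol(Z) + 4], tolerance = 1e-10)
})

test_that("a localized carrier effect shows up in the right environment band", {
  hits <- 0
  for (s in 1:20) {
    set.seed(130 + s)
    n <- 240
    g <- rbinom(n, 1, 0.4)
    env <- factor(sample(c("<18", "18-25", ">=25"), n, TRUE),
                  levels = c("<18", "18-25", ">=25"))
    Z <- random_covariates(n)[, c("height", "fev1_baseline",
                                  "log_endotoxin")]
    y <- -4 - 25 * g * (env == "18-25") + rnorm(n, 0, 10)
    fit <- fit_gene_environment(y, g, env, Z)
    cells <- fit$cells
    carrier <- cells[cells$level_a == 1, ]
    if (which.min(carrier$p) == match("18-25", carrier$level_b))
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the null F-test is calibrated across seeds", {
  pvals <- vapply(1:60, function(s) {
    set.seed(200 + s)
    n <- 200
    g <- rbinom(n, 1, 0.4)
    env <- factor(sample(c("a", "b", "c"), n, TRUE))
    Z <- random_covariates(n)[, c("height", "fev1_baseline")]
    y <- -4 - 5 * g + rnorm(n, 0, 8)
    fit_gene_environment(y, g, env, Z)$interaction_p
  }, numeric(1))
  expect_gt(mean(pvals <= 0.5), 0.35)
  expect_lt(mean(pvals <= 0.5), 0.65)
  expect_lte(mean(pvals <= 0.05), 0.15)
})

test_that("the pairwise scan enumerates families and attaches q-values", {
  cfg <- sim_config(n_subjects = 150, n_snps = 12,
                    interaction_effects = list(
                      list(type = "snp_snp", a = 1, b = 2, effect = -30)),
                    within_subject_sd = 60, seed = 127)
  ch <- simulate_cohort(cfg)
  sl <- estimate_all_slopes(ch$phenotype)
  ids <- ch$panel$snps$snp_id[1:10]
  gg <- pairwise_interaction_scan(ch$panel, sl, ch$covariates, ids)
  expect_identical(nrow(gg$table), 45L)  # C(10, 2)
  ok <- !is.na(gg$table$interaction_p)
  expect_equal(gg$table$q[ok], bh_fdr(gg$table$interaction_p[ok]))
  # the planted pair should sit at the top of the family
  top <- gg$table[which.min(gg$table$q), ]
  expect_setequal(c(top$factor_a, top$factor_b), ids[1:2])

  two <- pairwise_interaction_scan(ch$panel, sl, ch$covariates, ids[1:2])
  expect_identical(nrow(two$table), 1L)
  expect_equal(two$table$q, two$table$interaction_p)

  ge <- pairwise_interaction_scan(ch$panel, sl, ch$covariates, ids,
                                  env = "age")
  expect_identical(nrow(ge$table), 10L)
  expect_true(all(ge$table$factor_b == "age"))
  ee <- pairwise_interaction_scan(ch$panel, sl, ch$covariates, ids,
                                  env = "endotoxin")
  expect_identical(nrow(ee$table), 10L)
})

test_that("age bands and endotoxin strata follow the boundary conventions", {
  b <- age_bands(c(16, 17.99, 18, 24.99, 25, 40))
  expect_identical(as.character(b),
                   c("<18", "<18", "18-25", "18-25", ">=25", ">=25"))
  g <- endotoxin_groups(c(100, 163, 164, 500), cutoff = 163)
  expect_identical(as.character(g), c("low", "low", "high", "high"))
})
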