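# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for the exact HWE test,
# textbook normal equations for every regression check.

# exact HWE P by direct enumeration of all heterozygote counts consistent
# with the observed allele counts, in log-factorial space
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n - n_a
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (min(n_a, n_b) - h) / 2
    nbb <- n - naa - h
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# OLS coefficient vector, standard errors and two-sided t-test P-values via
# explicit normal equations (X'X)^-1 X'y
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  inv <- solve(XtX)
  beta <- as.vector(inv %*% crossprod(X, y))
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- unname(sqrt(sigma2 * diag(inv)))
  tval <- beta / se
  list(beta = unname(beta), se = se, p = unname(2 * pt(-abs(tval), df)),
       df = df)
}

# tiny genotype panel built by hand
toy_panel <- function(calls, chrom = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- as.character(rep_len(1:22, m))
  snps <- data.frame(snp_id = paste0("rs", seq_len(m)), chromosome = chrom,
                     position = seq_len(m) * 100L, allele_a = "A",
                     allele_b = "C", stringsAsFactors = FALSE)
  genotype_panel(calls, snps, sprintf("s%03d", seq_len(nrow(calls))))
}

# random covariate matrix in the cohort's units
random_covariates <- function(n) {
  cbind(height = rnorm(n, 160, 5.5), age = rnorm(n, 25, 7),
        fev1_baseline = rnorm(n, 2630, 350),
        log_endotoxin = rnorm(n, log(163), 0.5))
}
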