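#' Bootstrap stability validation of association hits
#'
#' Internal validation of top SNPs: subjects are resampled with replacement
#' (covariates and slope travel with the subject), the covariate-adjusted SNP
#' model is refitted in each replicate, and the proportion of replicates with
#' P at or below a predefined threshold is reported. A SNP whose proportion
#' reaches 0.80 is flagged stable (unlikely to be a false positive).
#' Degenerate replicates — constant genotype code or rank-deficient design —
#' count as non-significant rather than being redrawn, so they weigh against
#' stability.
#'
#' The genotype coding (minor allele, dominant dichotomy) is fixed from the
#' full sample; slopes are resampled as fixed per-subject quantities unless
#' \code{refit_slopes = TRUE}, in which case each replicate re-estimates the
#' slopes from the resampled subjects' visit records.
#'
#' @inheritParams assoc_scan
#' @param snp_ids character vector of SNP ids to validate (must be present in
#'   the panel).
#' @param n_boot number of bootstrap replicates (>= 1; 2,000 is the
#'   conventional choice).
#' @param p_threshold per-replicate significance threshold; default
#'   \code{0.05 / length(snp_ids)} (e.g. 0.005 when validating 10 SNPs).
#' @param seed integer seed; counts are reproduced exactly under a fixed
#'   seed.
#' @param stable_min proportion required to flag a SNP stable (default 0.80).
#' @param refit_slopes re-estimate per-subject slopes inside each replicate
#'   (requires \code{pheno}).
#' @param pheno \code{longitudinal_phenotype}, only used when
#'   \code{refit_slopes = TRUE}.
#' @return data.frame of class \code{stability_result}: one row per SNP with
#'   snp_id, n_boot, p_threshold, n_significant, proportion, stable, seed.
#' @export
bootstrap_stability <- function(panel, slopes, cov, snp_ids,
                                model = c("dominant", "additive"),
                                n_boot = 2000, p_threshold = NULL, seed = 1,
                                stable_min = 0.80,
                                endotoxin = c("log_mean", "mean_log"),
                                refit_slopes = FALSE, pheno = NULL) {
  model <- match.arg(model)
  if (n_boot < 1) stop("n_boot must be >= 1")
  missing_snps <- setdiff(snp_ids, panel$snps$snp_id)
  if (length(missing_snps))
    stop("SNP(s) not in panel: ", paste(missing_snps, collapse = ", "))
  if (is.null(p_threshold)) p_threshold <- 0.05 / length(snp_ids)
  if (refit_slopes && is.null(pheno))
    stop("refit_slopes = TRUE requires pheno")
  al <- align_inputs(panel, slopes, cov)
  Zfull <- build_covariate_matrix(cov, endotoxin = endotoxin)
  Z <- Zfull[match(al$subjects, rownames(Zfull)), , drop = FALSE]
  y <- al$es
  n <- length(y)
  sub_panel <- panel_subset(panel, subjects = al$subjects, snps = snp_ids)
  codes <- lapply(seq_along(snp_ids), function(j)
    encode_genotype(sub_panel$calls[, j], model))
  visits <- if (refit_slopes)
    split(pheno[, c("month", "fev1")], pheno$subject)[al$subjects]

  old_seed <- .Random.seed_exists()
  set.seed(seed)
  n_sig <- integer(length(snp_ids))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    yb <- if (refit_slopes) {
      vapply(visits[idx], function(v) {
        if (length(unique(v$month)) < 2) return(NA_real_)
        estimate_slope(v$month, v$fev1)$es
      }, numeric(1))
    } else y[idx]
    Zb <- Z[idx, , drop = FALSE]
    for (j in seq_along(snp_ids)) {
      if (codes[[j]]$excluded) next
      gb <- codes[[j]]$code[idx]
      p <- .boot_snp_p(yb, gb, Zb)
      if (!is.na(p) && p <= p_threshold) n_sig[j] <- n_sig[j] + 1L
    }
  }
  on.exit(old_seed())
  structure(data.frame(
    snp_id = snp_ids, n_boot = n_boot, p_threshold = p_threshold,
    n_significant = n_sig, proportion = n_sig / n_boot,
    stable = n_sig / n_boot >= stable_min, seed = seed,
    stringsAsFactors = FALSE), class = c("stability_result", "data.frame"))
}

# genotype-coefficient P for one bootstrap replicate; NA when degenerate
.boot_snp_p <- function(y, g, Z) {
  cc <- !is.na(y) & !is.na(g) & stats::complete.cases(Z)
  y <- y[cc]; g <- g[cc]; Z <- Z[cc, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(Z) + 2 || stats::var(g) == 0) return(NA_real_)
  X <- cbind(1, g, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NA_real_)
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  df <- n - ncol(X)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sum(resid^2) / df * XtXinv[2, 2])
  2 * stats::pt(-abs(beta[2] / se), df)
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("bootstrap stability: %d replicates, threshold P <= %.4g\n",
              x$n_boot[1], x$p_threshold[1]))
  print.data.frame(x[, c("snp_id", "n_significant", "proportion", "stable")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}
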