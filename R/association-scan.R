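#' Encode a SNP's genotype calls under a genetic model
#'
#' The minor allele is determined from the non-missing calls of the column
#' (ties at MAF 0.5 resolve to \code{allele_b}). Dominant coding is 0 for the
#' major-allele homozygote and 1 for any minor-allele carrier; additive coding
#' is the minor-allele count 0/1/2. Under the additive model, SNPs whose
#' rare-homozygote frequency among non-missing calls is at or below 5% are
#' flagged for exclusion (lack of statistical robustness); monomorphic SNPs
#' are flagged under either model.
#'
#' @param calls integer vector of allele_b counts (0/1/2/NA) for one SNP.
#' @param model \code{"dominant"} or \code{"additive"}.
#' @param rare_hom_max additive-model exclusion bound on rare-homozygote
#'   frequency (default 0.05; exclusion when frequency <= bound).
#' @return list with \code{code} (numeric vector, NA preserved),
#'   \code{excluded} (flag) and \code{reason}.
#' @export
encode_genotype <- function(calls, model = c("dominant", "additive"),
                            rare_hom_max = 0.05) {
  model <- match.arg(model)
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0)
    return(list(code = rep(NA_real_, length(calls)), excluded = TRUE,
                reason = "all calls missing"))
  if (length(unique(obs)) == 1)
    return(list(code = rep(NA_real_, length(calls)), excluded = TRUE,
                reason = "monomorphic"))
  p_b <- sum(obs) / (2 * length(obs))
  minor_count <- if (p_b <= 0.5) calls else 2L - calls
  if (model == "dominant") {
    code <- as.numeric(minor_count >= 1)
    return(list(code = code, excluded = FALSE, reason = NA_character_))
  }
  rare_hom_freq <- mean(minor_count[!is.na(minor_count)] == 2)
  excluded <- rare_hom_freq <= rare_hom_max
  list(code = as.numeric(minor_count), excluded = excluded,
       reason = if (excluded) "rare homozygote frequency <= bound"
                else NA_character_)
}

#' Covariate design for association models
#'
#' Builds the adjustment matrix used throughout: height (cm), age (years),
#' baseline FEV1 (ml, the observed month-0 value) and the log-scale average
#' endotoxin exposure. The endotoxin summary defaults to the log of the
#' across-visit mean (\code{"log_mean"}); \code{"mean_log"} averages the
#' per-visit logs instead. Optional principal-component scores can be
#' appended for sensitivity analyses.
#'
#' @param cov a \code{\link{covariate_table}}.
#' @param endotoxin \code{"log_mean"} or \code{"mean_log"}.
#' @param pcs optional numeric matrix of PC scores with rownames matching
#'   subject ids.
#' @return numeric matrix, one row per subject (rownames = subject ids),
#'   columns \code{height}, \code{age}, \code{fev1_baseline},
#'   \code{log_endotoxin} (+ \code{PC1}, ...). Attribute
#'   \code{endotoxin_method} records the summary order used.
#' @export
build_covariate_matrix <- function(cov, endotoxin = c("log_mean", "mean_log"),
                                   pcs = NULL) {
  endotoxin <- match.arg(endotoxin)
  stopifnot(inherits(cov, "covariate_table"))
  le <- log_endotoxin(cov, method = endotoxin)
  Z <- cbind(height = cov$data$height, age = cov$data$age,
             fev1_baseline = cov$data$fev1_baseline, log_endotoxin = le)
  rownames(Z) <- cov$data$subject
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    idx <- match(rownames(Z), rownames(pcs))
    if (anyNA(idx)) stop("PC scores missing for some subjects")
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    Z <- cbind(Z, pcs[idx, , drop = FALSE])
  }
  attr(Z, "endotoxin_method") <- endotoxin
  Z
}

#' Covariate-adjusted linear model for one SNP
#'
#' OLS of the slope phenotype on an intercept, the genotype code and the
#' covariates, on complete cases (subjects missing the call or any covariate
#' are dropped). The reported beta, SE and two-sided t-test P belong to the
#' genotype coefficient (df = n - k - 2 for k covariates). Unadjusted
#' mean +/- SD of the slope is reported for the reference (code 0) and
#' carrier (code > 0) groups. Negative beta means carriers decline faster.
#'
#' @param es numeric slope vector (ml/month).
#' @param code numeric genotype code vector (aligned, NA = missing call).
#' @param covariates numeric covariate matrix (aligned rows).
#' @param snp_id,model labels copied into the result row.
#' @return one-row data.frame with columns snp_id, model, n_ref, n_carrier,
#'   mean_ref, sd_ref, mean_carrier, sd_carrier, beta, se, p, excluded,
#'   reason.
#' @export
fit_snp_model <- function(es, code, covariates, snp_id = NA_character_,
                          model = NA_character_) {
  covariates <- as.matrix(covariates)
  stopifnot(length(es) == length(code), nrow(covariates) == length(es))
  cc <- !is.na(es) & !is.na(code) & stats::complete.cases(covariates)
  y <- es[cc]; g <- code[cc]; Z <- covariates[cc, , drop = FALSE]
  n <- length(y)
  k <- ncol(Z)
  grp <- g > 0
  res <- data.frame(
    snp_id = snp_id, model = model,
    n_ref = sum(!grp), n_carrier = sum(grp),
    mean_ref = if (any(!grp)) mean(y[!grp]) else NA_real_,
    sd_ref = if (sum(!grp) > 1) stats::sd(y[!grp]) else NA_real_,
    mean_carrier = if (any(grp)) mean(y[grp]) else NA_real_,
    sd_carrier = if (sum(grp) > 1) stats::sd(y[grp]) else NA_real_,
    beta = NA_real_, se = NA_real_, p = NA_real_,
    excluded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)
  if (n <= k + 2) {
    res$excluded <- TRUE; res$reason <- "insufficient complete cases"
    return(res)
  }
  X <- cbind(`(Intercept)` = 1, code = g, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    res$excluded <- TRUE; res$reason <- "rank-deficient design"
    return(res)
  }
  beta_hat <- qr.coef(qx, y)
  resid <- y - X %*% beta_hat
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  res$beta <- beta_hat[["code"]]
  res$se <- se
  # floor keeps P in (0, 1] even for numerically perfect (noise-free) fits
  res$p <- max(2 * stats::pt(-abs(res$beta / se), df),
               .Machine$double.xmin)
  res
}

# intersect subjects across panel, slope set and covariate table,
# preserving panel order
align_inputs <- function(panel, slopes, cov) {
  subjects <- intersect(intersect(panel$subjects, slopes$subject),
                        cov$data$subject)
  if (length(subjects) == 0)
    stop("cohort mismatch: no subjects shared by panel, slopes and covariates")
  subjects <- panel$subjects[panel$subjects %in% subjects]
  list(subjects = subjects,
       es = slopes$es[match(subjects, slopes$subject)],
       cov_rows = match(subjects, cov$data$subject))
}

#' Covariate-adjusted association scan over a panel
#'
#' Fits \code{\link{fit_snp_model}} for every SNP in the panel under the
#' chosen genetic model, on the subjects shared by panel, slope set and
#' covariate table. Results include per-SNP exclusion flags (monomorphic,
#' additive rare-homozygote rule, rank deficiency) and a scan summary with
#' the genomic-control inflation factor computed from the tested P-values.
#'
#' @param panel post-QC \code{genotype_panel}.
#' @param slopes a \code{slope_set} from \code{\link{estimate_all_slopes}}.
#' @param cov a \code{covariate_table}.
#' @param model \code{"dominant"} or \code{"additive"}.
#' @param endotoxin endotoxin summary order, see
#'   \code{\link{build_covariate_matrix}}.
#' @param pcs optional PC score matrix passed through to the design.
#' @param min_age optional lower age bound (years); subjects younger than
#'   this are excluded before fitting (adults-only sensitivity subset).
#' @return object of class \code{assoc_scan}: list with \code{results}
#'   (data.frame, one row per SNP), \code{summary} (lambda_gc, n_tested,
#'   n_excluded, n_subjects) and \code{meta}.
#' @export
assoc_scan <- function(panel, slopes, cov, model = c("dominant", "additive"),
                       endotoxin = c("log_mean", "mean_log"), pcs = NULL,
                       min_age = NULL) {
  model <- match.arg(model)
  al <- align_inputs(panel, slopes, cov)
  Zfull <- build_covariate_matrix(cov, endotoxin = endotoxin, pcs = pcs)
  Z <- Zfull[match(al$subjects, rownames(Zfull)), , drop = FALSE]
  y <- al$es
  if (!is.null(min_age)) {
    keepers <- Z[, "age"] >= min_age
    Z <- Z[keepers, , drop = FALSE]
    y <- y[keepers]
    al$subjects <- al$subjects[keepers]
  }
  sub_panel <- panel_subset(panel, subjects = al$subjects)
  m <- nrow(sub_panel$snps)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    enc <- encode_genotype(sub_panel$calls[, j], model)
    if (enc$excluded) {
      rows[[j]] <- fit_snp_model(y, rep(NA_real_, length(y)) , Z,
                                 snp_id = sub_panel$snps$snp_id[j],
                                 model = model)
      rows[[j]]$excluded <- TRUE
      rows[[j]]$reason <- enc$reason
      rows[[j]]$n_ref <- rows[[j]]$n_carrier <- 0L
      rows[[j]][c("mean_ref", "sd_ref", "mean_carrier", "sd_carrier")] <-
        NA_real_
    } else {
      rows[[j]] <- fit_snp_model(y, enc$code, Z,
                                 snp_id = sub_panel$snps$snp_id[j],
                                 model = model)
    }
  }
  results <- do.call(rbind, rows)
  results$chromosome <- sub_panel$snps$chromosome
  results$position <- sub_panel$snps$position
  tested <- !results$excluded & !is.na(results$p)
  lambda <- if (any(tested)) genomic_control_lambda(results$p[tested])
            else NA_real_
  structure(list(
    results = results,
    summary = list(lambda_gc = lambda, n_tested = sum(tested),
                   n_excluded = sum(!tested),
                   n_subjects = length(al$subjects)),
    meta = list(model = model,
                endotoxin_method = attr(Zfull, "endotoxin_method"),
                covariates = colnames(Z), min_age = min_age)),
    class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("assoc_scan (%s model): %d SNPs tested, %d excluded, %d subjects\n",
              x$meta$model, s$n_tested, s$n_excluded, s$n_subjects))
  cat(sprintf("  genomic-control lambda: %.3f\n", s$lambda_gc))
  cat(sprintf("  adjusted for: %s (endotoxin: %s)\n",
              paste(x$meta$covariates, collapse = ", "),
              x$meta$endotoxin_method))
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, n_top = 10, ...) {
  print(object)
  res <- object$results[!object$results$excluded, ]
  res <- res[order(res$p), ]
  cat("top SNPs:\n")
  print.data.frame(utils::head(
    res[, c("snp_id", "n_ref", "n_carrier", "beta", "se", "p")], n_top),
    row.names = FALSE, digits = 4)
  invisible(res)
}

#' Manhattan-style plot of an association scan
#'
#' @param x an \code{assoc_scan}.
#' @param threshold optional per-test significance threshold drawn as a
#'   horizontal line.
#' @param ... passed to \code{plot}.
#' @export
plot.assoc_scan <- function(x, threshold = NULL, ...) {
  res <- x$results[!x$results$excluded & !is.na(x$results$p), ]
  chrom <- suppressWarnings(as.integer(res$chromosome))
  ord <- order(chrom, res$position)
  res <- res[ord, ]
  col <- 1 + (as.integer(factor(res$chromosome)) %% 2)
  graphics::plot(seq_len(nrow(res)), -log10(res$p), col = c("grey30",
                 "steelblue")[col], pch = 20, xlab = "SNP (genome order)",
                 ylab = expression(-log[10](italic(P))), ...)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' lambda = median of the 1-df chi-square statistics implied by the P-values,
#' divided by the null median 0.4549364. Values near 1 indicate no
#' stratification inflation.
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @return lambda (dimensionless, > 0).
#' @export
genomic_control_lambda <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty P-value list")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("P-values must lie in (0, 1]")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Manhattan-ready export of scan results
#'
#' Writes chromosome, position and -log10(P) (plus the full result columns)
#' as TSV, sorted by P.
#'
#' @param scan an \code{assoc_scan}.
#' @param path output TSV path.
#' @export
export_scan_results <- function(scan, path) {
  res <- scan$results
  res$neg_log10_p <- -log10(res$p)
  res <- res[order(res$p), ]
  write_results_table(res, path)
  invisible(res)
}
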