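#' Derive the risk side of each SNP's dominant dichotomy
#'
#' The risk genotype group of a SNP is read off the sign of its adjusted
#' dominant-model beta: carriers are the risk side when beta < 0 (carriers
#' decline faster), noncarriers when beta > 0. A zero beta leaves the risk
#' side undefined and is an error.
#'
#' @param results an \code{assoc_scan} (dominant model) or a data.frame with
#'   columns \code{snp_id} and \code{beta}.
#' @return data.frame of class \code{risk_coding} with columns \code{snp_id}
#'   and \code{risk_side} ("carrier" or "noncarrier").
#' @export
derive_risk_coding <- function(results) {
  if (inherits(results, "assoc_scan")) results <- results$results
  stopifnot(all(c("snp_id", "beta") %in% names(results)))
  beta <- results$beta
  if (any(!is.finite(beta)))
    stop("risk coding requires finite dominant-model betas for every SNP")
  if (any(beta == 0))
    stop("zero beta at SNP ",
         paste(results$snp_id[beta == 0], collapse = ", "),
         ": risk side undefined")
  structure(data.frame(
    snp_id = results$snp_id,
    risk_side = ifelse(beta < 0, "carrier", "noncarrier"),
    stringsAsFactors = FALSE), class = c("risk_coding", "data.frame"))
}

#' Counted genetic risk score
#'
#' Per subject, the number of coded SNPs at which the subject's
#' dominant-dichotomy group (carrier of the minor allele, or not) is the risk
#' side. Missing genotypes contribute 0 — the score is a lower bound — and
#' are counted separately.
#'
#' @param panel a \code{genotype_panel} containing every coded SNP.
#' @param coding a \code{\link{derive_risk_coding}} result.
#' @return data.frame of class \code{grs_scores}: \code{subject}, \code{grs}
#'   (integer 0..k), \code{n_missing}.
#' @export
compute_grs <- function(panel, coding) {
  stopifnot(inherits(coding, "risk_coding"))
  missing_snps <- setdiff(coding$snp_id, panel$snps$snp_id)
  if (length(missing_snps))
    stop("coded SNP(s) absent from panel: ",
         paste(missing_snps, collapse = ", "))
  sub <- panel_subset(panel, snps = coding$snp_id)
  k <- nrow(coding)
  contrib <- matrix(0L, length(sub$subjects), k)
  nmiss <- matrix(0L, length(sub$subjects), k)
  for (j in seq_len(k)) {
    code <- encode_genotype(sub$calls[, j], "dominant")$code
    carrier <- code >= 1
    risk <- if (coding$risk_side[j] == "carrier") carrier else !carrier
    risk[is.na(risk)] <- FALSE
    contrib[, j] <- as.integer(risk)
    nmiss[, j] <- as.integer(is.na(code))
  }
  structure(data.frame(subject = sub$subjects,
                       grs = as.integer(rowSums(contrib)),
                       n_missing = as.integer(rowSums(nmiss)),
                       stringsAsFactors = FALSE),
            class = c("grs_scores", "data.frame"))
}

#' Trend test of the slope phenotype on the genetic risk score
#'
#' OLS of the slope on the score as a single ordinal term plus covariates;
#' the trend P is the two-sided t-test of the score coefficient. Subjects
#' missing more than \code{max_missing_frac} of the coded SNPs are excluded
#' (their lower-bound score is unreliable). An optional per-category
#' parameterization (one coefficient per score value, reference = the lowest
#' observed score) is returned for coefficient plots.
#'
#' @param es numeric slope vector aligned with \code{grs}.
#' @param grs a \code{grs_scores} data.frame or an integer vector.
#' @param covariates numeric covariate matrix (aligned rows).
#' @param max_missing_frac exclusion bound for missing coded SNPs (default
#'   0.2; only applies when \code{grs} carries an \code{n_missing} column).
#' @param n_coded number of coded SNPs k (needed for the missingness rule
#'   when \code{grs} is a bare vector; inferred otherwise).
#' @return object of class \code{grs_fit}: list with \code{beta} (ml/month
#'   per risk genotype), \code{se}, \code{p_trend}, \code{n},
#'   \code{categories} (per-score coefficient table).
#' @export
grs_trend <- function(es, grs, covariates, max_missing_frac = 0.2,
                      n_coded = NULL) {
  covariates <- as.matrix(covariates)
  if (is.data.frame(grs)) {
    score <- grs$grs
    n_missing <- grs$n_missing
    if (is.null(n_coded)) n_coded <- max(score + n_missing)
  } else {
    score <- as.numeric(grs)
    n_missing <- rep(0L, length(score))
    if (is.null(n_coded)) n_coded <- max(score)
  }
  stopifnot(length(es) == length(score), nrow(covariates) == length(es))
  keep <- !is.na(es) & !is.na(score) & stats::complete.cases(covariates) &
    (n_coded == 0 | n_missing <= max_missing_frac * n_coded)
  y <- es[keep]; s <- score[keep]; Z <- covariates[keep, , drop = FALSE]
  if (length(unique(s)) < 2)
    stop("degenerate: risk score is constant among analyzed subjects")
  fit <- .ols_fit(y, cbind(1, grs = s, Z))
  if (!fit$ok) stop("rank-deficient trend design")
  # per-category parameterization for coefficient plots
  cats <- sort(unique(s))
  cat_tab <- data.frame(grs = cats, n = as.integer(table(factor(s, cats))),
                        beta = NA_real_, se = NA_real_, p = NA_real_)
  if (length(cats) > 1) {
    D <- sapply(cats[-1], function(c0) as.numeric(s == c0))
    cfit <- .ols_fit(y, cbind(1, Z, D))
    if (cfit$ok) {
      pos <- ncol(Z) + 1 + seq_len(ncol(D))
      cat_tab$beta[-1] <- unname(cfit$coef[pos])
      cat_tab$se[-1] <- unname(cfit$se[pos])
      cat_tab$p[-1] <- unname(cfit$p[pos])
    }
  }
  structure(list(beta = unname(fit$coef[2]), se = unname(fit$se[2]),
                 p_trend = unname(fit$p[2]), n = length(y),
                 categories = cat_tab), class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("GRS trend: beta = %.3f ml/month per risk genotype (se %.3f), P_trend = %.3g, n = %d\n",
              x$beta, x$se, x$p_trend, x$n))
  invisible(x)
}

#' Per-score coefficient plot for a GRS trend fit
#'
#' @param x a \code{grs_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.grs_fit <- function(x, ...) {
  ct <- x$categories
  lo <- ct$beta - 1.96 * ct$se
  hi <- ct$beta + 1.96 * ct$se
  graphics::plot(ct$grs, ct$beta, ylim = range(c(lo, hi, 0), na.rm = TRUE),
                 pch = 15, xlab = "genetic risk score",
                 ylab = "coefficient vs lowest score (ml/month)", ...)
  graphics::segments(ct$grs, lo, ct$grs, hi)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Stratified GRS trend and GRS-by-modifier interaction
#'
#' Fits the trend within each stratum (the stratifying covariate must be
#' absent from \code{covariates}); strata with fewer subjects than the model
#' needs are flagged and skipped. The interaction P comes from an F-test of
#' the score-by-stratum product terms in the pooled model.
#'
#' @inheritParams grs_trend
#' @param strata factor aligned with \code{es} (e.g. \code{\link{age_bands}}
#'   output or \code{\link{endotoxin_groups}} output).
#' @return object of class \code{grs_stratified}: list with
#'   \code{per_stratum} (data.frame: stratum, n, beta, se, p, flagged) and
#'   \code{interaction_p}.
#' @export
grs_stratified <- function(es, grs, covariates, strata,
                           max_missing_frac = 0.2, n_coded = NULL) {
  covariates <- as.matrix(covariates)
  strata <- droplevels(as.factor(strata))
  if (is.data.frame(grs)) {
    score <- grs$grs; n_missing <- grs$n_missing
    if (is.null(n_coded)) n_coded <- max(score + n_missing)
  } else {
    score <- as.numeric(grs); n_missing <- rep(0L, length(score))
    if (is.null(n_coded)) n_coded <- max(score)
  }
  keep <- !is.na(es) & !is.na(score) & !is.na(strata) &
    stats::complete.cases(covariates) &
    (n_coded == 0 | n_missing <= max_missing_frac * n_coded)
  y <- es[keep]; s <- score[keep]; st <- droplevels(strata[keep])
  Z <- covariates[keep, , drop = FALSE]
  k_model <- ncol(Z) + 2
  per <- data.frame(stratum = levels(st), n = NA_integer_, beta = NA_real_,
                    se = NA_real_, p = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per))) {
    inc <- st == per$stratum[i]
    per$n[i] <- sum(inc)
    if (sum(inc) < k_model + 1 || length(unique(s[inc])) < 2) {
      per$flagged[i] <- TRUE
      next
    }
    f <- .ols_fit(y[inc], cbind(1, grs = s[inc], Z[inc, , drop = FALSE]))
    if (!f$ok) { per$flagged[i] <- TRUE; next }
    per$beta[i] <- unname(f$coef[2])
    per$se[i] <- unname(f$se[2])
    per$p[i] <- unname(f$p[2])
  }
  # pooled model: score * strata product-term F-test
  int_p <- NA_real_
  int_betas <- NULL
  if (nlevels(st) >= 2) {
    Sdum <- stats::model.matrix(~ st)[, -1, drop = FALSE]
    X0 <- cbind(1, Z, grs = s, Sdum)
    X1 <- cbind(X0, s * Sdum)
    f0 <- .ols_fit(y, X0); f1 <- .ols_fit(y, X1)
    if (f0$ok && f1$ok) {
      ft <- .nested_f_test(f0$rss, f1$rss, ncol(X1) - ncol(X0), f1$df)
      int_p <- ft$p
      int_betas <- unname(f1$coef[(ncol(X0) + 1):ncol(X1)])
    }
  }
  structure(list(per_stratum = per, interaction_p = int_p,
                 interaction_betas = int_betas),
            class = "grs_stratified")
}

#' @export
print.grs_stratified <- function(x, ...) {
  cat(sprintf("GRS stratified analysis (interaction P = %.3g)\n",
              x$interaction_p))
  print.data.frame(x$per_stratum, row.names = FALSE, digits = 4)
  invisible(x)
}
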