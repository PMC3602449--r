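#' Permutation null distribution for study-wide error control
#'
#' Rebuilds the full association scan under the null hypothesis of no
#' genotype effect while preserving both the covariate structure of the
#' phenotype model and the correlation (linkage disequilibrium) between SNPs.
#' By default the Freedman-Lane scheme is used: the slope phenotype's
#' covariate-adjusted residuals are permuted across subjects and the fitted
#' covariate part is added back; genotype columns are never permuted
#' independently. The per-permutation minimum P-value across SNPs yields the
#' family-wise error calibration; the pooled null P-values yield the
#' permutation FDR.
#'
#' Only SNPs that the observed scan would test are included (monomorphic and
#' additive rare-homozygote exclusions are dropped). Missing genotype calls
#' are handled per missingness pattern with complete-case refitting.
#'
#' @inheritParams assoc_scan
#' @param n_perm number of permutation replicates (>= 100; smaller values
#'   make tail quantiles unstable and are refused).
#' @param seed integer seed; the null is bit-reproducible given the seed.
#' @param scheme \code{"freedman_lane"} (default) or \code{"raw"}
#'   (raw-phenotype shuffle).
#' @return object of class \code{perm_null}: list with \code{minp}
#'   (per-permutation minimum P), \code{null_p_sorted} (pooled sorted null
#'   P-values), \code{n_perm}, \code{n_snps_tested}, \code{seed},
#'   \code{scheme}.
#' @export
build_permutation_null <- function(panel, slopes, cov,
                                   model = c("dominant", "additive"),
                                   n_perm = 1000, seed = 1,
                                   endotoxin = c("log_mean", "mean_log"),
                                   scheme = c("freedman_lane", "raw")) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  if (n_perm < 100)
    stop("n_perm must be >= 100 (tail quantiles unstable below that)")
  al <- align_inputs(panel, slopes, cov)
  Zfull <- build_covariate_matrix(cov, endotoxin = endotoxin)
  Z <- cbind(1, Zfull[match(al$subjects, rownames(Zfull)), , drop = FALSE])
  y <- al$es
  n <- length(y)
  sub_panel <- panel_subset(panel, subjects = al$subjects)
  m_all <- nrow(sub_panel$snps)
  G <- matrix(NA_real_, n, m_all)
  keep <- logical(m_all)
  for (j in seq_len(m_all)) {
    enc <- encode_genotype(sub_panel$calls[, j], model)
    if (!enc$excluded) {
      G[, j] <- enc$code
      keep[j] <- TRUE
    }
  }
  G <- G[, keep, drop = FALSE]
  m <- ncol(G)
  if (m == 0) stop("no testable SNPs in panel")

  qz <- qr(Z)
  Q <- qr.Q(qz)
  fit_y <- Q %*% crossprod(Q, y)
  resid_y <- y - fit_y

  old_seed <- .Random.seed_exists()
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  on.exit(old_seed())

  Ystar <- if (scheme == "freedman_lane") {
    matrix(resid_y[perm_idx], n, n_perm) + as.vector(fit_y)
  } else {
    matrix(y[perm_idx], n, n_perm)
  }

  pmat <- .null_pvalue_matrix(G, Ystar, Z, Q)
  minp <- apply(pmat, 2, min, na.rm = TRUE)
  structure(list(minp = minp,
                 null_p_sorted = sort(as.vector(pmat[!is.na(pmat)])),
                 n_perm = n_perm, n_snps_tested = m, seed = seed,
                 scheme = scheme, model = model),
            class = "perm_null")
}

# restore-RNG helper: returns a function that puts .Random.seed back
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# m x n_perm matrix of null P-values for genotype matrix G (n x m, NAs
# allowed) against permuted phenotypes Ystar (n x n_perm), adjusting for
# design Z (with intercept; Q = orthonormal basis of col(Z)).
# SNPs are grouped by missingness pattern; within a pattern everything is
# dense matrix algebra (Frisch-Waugh-Lovell residualization).
.null_pvalue_matrix <- function(G, Ystar, Z, Q = qr.Q(qr(Z))) {
  n <- nrow(G); m <- ncol(G); n_perm <- ncol(Ystar)
  pmat <- matrix(NA_real_, m, n_perm)
  miss <- is.na(G)
  pattern <- apply(miss, 2, function(v)
    if (!any(v)) "" else paste(which(v), collapse = ","))
  for (pat in unique(pattern)) {
    cols <- which(pattern == pat)
    s <- if (pat == "") seq_len(n) else setdiff(seq_len(n),
                                                as.integer(strsplit(pat, ",")[[1]]))
    ns <- length(s)
    Zs <- Z[s, , drop = FALSE]
    df <- ns - ncol(Zs) - 1
    if (df <= 0) next
    Qs <- if (pat == "") Q else qr.Q(qr(Zs))
    Gs <- G[s, cols, drop = FALSE]
    RG <- Gs - Qs %*% crossprod(Qs, Gs)
    sgg <- colSums(RG^2)
    ok <- sgg > 1e-10 * ns
    Ys <- Ystar[s, , drop = FALSE]
    RY <- Ys - Qs %*% crossprod(Qs, Ys)
    ryy <- colSums(RY^2)                       # length n_perm
    B <- crossprod(RG, RY) / sgg               # |cols| x n_perm
    expl <- B^2 * sgg                          # explained SS
    rss <- sweep(-expl, 2, ryy, "+")
    rss[rss < 0] <- 0
    tstat <- B * sqrt(sgg) * sqrt(df) / sqrt(rss)
    pm <- 2 * stats::pt(-abs(tstat), df)
    pm[!ok, ] <- NA_real_
    pmat[cols, ] <- pm
  }
  pmat
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("perm_null: %d permutations x %d SNPs (%s scheme, %s model, seed %d)\n",
              x$n_perm, x$n_snps_tested, x$scheme, x$model, x$seed))
  cat(sprintf("  min-P distribution: median %.3g, 5%% quantile %.3g\n",
              stats::median(x$minp), stats::quantile(x$minp, 0.05)))
  invisible(x)
}

#' Family-wise error threshold from a permutation null
#'
#' The per-test P-value threshold controlling the study-wide FWER at
#' \code{alpha}: the lower-tail \code{alpha}-quantile of the permutation
#' min-P distribution. Declaring any SNP with observed P at or below this
#' threshold keeps the probability of any false positive at \code{alpha}
#' under the permutation null.
#'
#' @param null a \code{perm_null}.
#' @param alpha target FWER in (0, 1].
#' @return per-test P threshold.
#' @export
fwer_threshold <- function(null, alpha) {
  stopifnot(inherits(null, "perm_null"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  unname(stats::quantile(null$minp, alpha, type = 1))
}

#' Permutation-based FDR q-values
#'
#' For each observed P-value p, q = (average number of null P-values <= p per
#' permutation) / (number of observed P-values <= p), capped at 1 and made
#' monotone non-decreasing in p by a cumulative minimum from the largest p
#' downward.
#'
#' @param observed_p observed P-values from the same scan configuration that
#'   built the null.
#' @param null a \code{perm_null}.
#' @return numeric q-values aligned with \code{observed_p}.
#' @export
permutation_fdr <- function(observed_p, null) {
  stopifnot(inherits(null, "perm_null"))
  if (any(is.na(observed_p)) || any(observed_p <= 0 | observed_p > 1))
    stop("observed P-values must lie in (0, 1]")
  ord <- order(observed_p)
  p_sorted <- observed_p[ord]
  null_le <- findInterval(p_sorted, null$null_p_sorted)  # count null <= p
  expected_false <- null_le / null$n_perm
  # ties: every copy of a tied p counts the full tied block as declared
  n_declared <- findInterval(p_sorted, p_sorted)
  q <- pmin(1, expected_false / n_declared)
  q <- rev(cummin(rev(q)))
  out <- numeric(length(q))
  out[ord] <- q
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values q_(i) = min over j >= i of m * p_(j) / j, as used for the
#' interaction-family corrections.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values aligned with the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty P-value list")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("P-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
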