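#' Quality-control thresholds
#'
#' Bundle of the filter thresholds applied by \code{\link{snp_filter}} and
#' \code{\link{sample_filter}}. Boundary conventions are deliberately
#' asymmetric: SNPs are removed when call rate is \emph{at or below}
#' \code{snp_call_rate}, subjects when call rate is \emph{strictly below}
#' \code{subject_call_rate}.
#'
#' @param snp_call_rate remove a SNP if its call rate is <= this (default
#'   0.95).
#' @param maf_min remove a SNP if its minor allele frequency is < this
#'   (default 0.05).
#' @param hwe_p_min remove a SNP if its exact Hardy-Weinberg P is < this
#'   (default 0.001).
#' @param subject_call_rate remove a subject if its call rate is < this
#'   (default 0.95).
#' @param relatedness_ibs_max flag a subject pair as cryptically related if
#'   their mean identity-by-state sharing exceeds this (default 0.9, a
#'   stand-in for a pi-hat screen).
#' @param outlier_sd remove a subject lying more than this many SDs from the
#'   mean on any retained principal component (default 6, the EIGENSTRAT
#'   convention).
#' @param n_pcs number of top principal components examined for outliers
#'   (default 10).
#' @return list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, maf_min = 0.05,
                          hwe_p_min = 0.001, subject_call_rate = 0.95,
                          relatedness_ibs_max = 0.9, outlier_sd = 6,
                          n_pcs = 10) {
  frac <- c(snp_call_rate = snp_call_rate, maf_min = maf_min,
            hwe_p_min = hwe_p_min, subject_call_rate = subject_call_rate,
            relatedness_ibs_max = relatedness_ibs_max)
  if (any(frac <= 0 | frac >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  if (outlier_sd <= 0) stop("outlier_sd must be positive")
  structure(list(snp_call_rate = snp_call_rate, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, subject_call_rate = subject_call_rate,
                 relatedness_ibs_max = relatedness_ibs_max,
                 outlier_sd = outlier_sd, n_pcs = n_pcs),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on a biallelic genotype table: given the observed
#' minor-allele count, the two-sided P-value sums the probabilities of every
#' heterozygote count whose conditional probability does not exceed that of
#' the observed table. Probabilities follow the hypergeometric-type
#' distribution of heterozygote counts under random mating, evaluated by a
#' numerically stable recurrence.
#'
#' @param n_hom_minor,n_het,n_hom_major non-negative genotype counts.
#' @return exact P-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # conditional mode: P = 1
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  if (any(c(n_hom_minor, n_het, n_hom_major) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom_minor + n_het + n_hom_major
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2L * n_hom_minor + n_het          # minor allele copies
  n_b <- 2L * n - n_a
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  if (n_a == 0L) return(1)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2L, n_a, by = 2L)
  probs <- numeric(length(hets))
  # start at the (approximate) conditional mode and recurse outward:
  # P(h+2)/P(h) = 4 * naa * nbb / ((h+2) * (h+1))
  mode_idx <- which.min(abs(hets - n_a * n_b / (2 * n - 1)))
  probs[mode_idx] <- 1
  if (mode_idx < length(hets)) {
    for (i in (mode_idx + 1):length(hets)) {
      h <- hets[i - 1]
      naa <- (n_a - h) / 2
      nbb <- (n_b - h) / 2
      probs[i] <- probs[i - 1] * 4 * naa * nbb / ((h + 2) * (h + 1))
    }
  }
  if (mode_idx > 1) {
    for (i in (mode_idx - 1):1) {
      h <- hets[i + 1]
      naa <- (n_a - h) / 2 + 1
      nbb <- (n_b - h) / 2 + 1
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * naa * nbb)
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele count")
  # tolerance guards ties against floating rounding
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply the SNP-level quality-control cascade
#'
#' Filters are applied sequentially in the fixed order: non-autosomal
#' chromosome, call rate at or below threshold, minor allele frequency below
#' threshold, exact Hardy-Weinberg P below threshold. Each SNP is counted
#' under the first criterion it fails; MAF and HWE are computed on non-missing
#' calls only.
#'
#' @param panel a \code{genotype_panel}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with elements \code{panel} (survivors) and \code{report}
#'   (a \code{qc_report}).
#' @export
snp_filter <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$snps) == 0) stop("empty panel")
  autosomal <- panel$snps$chromosome %in% as.character(1:22)
  n_nonauto <- sum(!autosomal)
  keep <- which(autosomal)

  cr <- snp_call_rate(panel)[keep]
  fail_cr <- cr <= thresholds$snp_call_rate
  n_cr <- sum(fail_cr)
  keep <- keep[!fail_cr]

  maf <- snp_maf(panel)[keep]
  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  n_maf <- sum(fail_maf)
  keep <- keep[!fail_maf]

  gc <- genotype_counts(panel)[keep, , drop = FALSE]
  hwe_p <- vapply(seq_len(nrow(gc)), function(i)
    hwe_exact_test(gc$n_hom_minor[i], gc$n_het[i], gc$n_hom_major[i]),
    numeric(1))
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  n_hwe <- sum(fail_hwe)
  keep <- keep[!fail_hwe]

  report <- qc_report(
    axis = "snp",
    steps = data.frame(
      criterion = c("non-autosomal", "call rate", "MAF", "HWE"),
      removed = c(n_nonauto, n_cr, n_maf, n_hwe)),
    n_input = nrow(panel$snps), n_survivors = length(keep),
    survivors = c(length(panel$subjects), length(keep)))
  list(panel = panel_subset(panel, snps = keep), report = report)
}

#' Apply the sample-level quality-control cascade
#'
#' Removes, in order: subjects with genotyping call rate below threshold; one
#' member of each cryptically related pair (mean identity-by-state sharing
#' above threshold; the lower-call-rate member is dropped, ties broken by
#' removing the later subject); and principal-component outliers (beyond
#' \code{outlier_sd} SDs from the mean on any of the top \code{n_pcs}
#' components of the standardized genotype matrix). Intended to run after
#' \code{\link{snp_filter}}.
#'
#' @inheritParams snp_filter
#' @return list with elements \code{panel} and \code{report}.
#' @export
sample_filter <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  n0 <- length(panel$subjects)
  cr_all <- subject_call_rate(panel)
  keep <- which(cr_all >= thresholds$subject_call_rate)
  n_cr <- n0 - length(keep)

  # cryptic relatedness: mean IBS over non-missing SNP pairs
  related_removed <- integer(0)
  if (length(keep) >= 2) {
    ibs <- ibs_matrix(panel$calls[keep, , drop = FALSE])
    pairs <- which(upper.tri(ibs) & ibs > thresholds$relatedness_ibs_max,
                   arr.ind = TRUE)
    if (nrow(pairs)) {
      drop <- logical(length(keep))
      cr <- cr_all[keep]
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (drop[i] || drop[j]) next
        drop_j <- if (cr[i] == cr[j]) TRUE else cr[j] < cr[i]
        if (drop_j) drop[j] <- TRUE else drop[i] <- TRUE
      }
      related_removed <- keep[drop]
      keep <- keep[!drop]
    }
  }
  n_rel <- length(related_removed)

  # PCA outliers
  n_out <- 0L
  if (length(keep) < 3) {
    warning("fewer than 3 subjects remain; PCA outlier step skipped")
  } else {
    scores <- genotype_pca(panel$calls[keep, , drop = FALSE],
                           n_pcs = thresholds$n_pcs)
    z <- abs(scale(scores))
    out <- apply(z > thresholds$outlier_sd, 1, any)
    n_out <- sum(out)
    keep <- keep[!out]
  }

  report <- qc_report(
    axis = "subject",
    steps = data.frame(
      criterion = c("call rate", "relatedness", "PCA outlier"),
      removed = c(n_cr, n_rel, n_out)),
    n_input = n0, n_survivors = length(keep),
    survivors = c(length(keep), nrow(panel$snps)))
  list(panel = panel_subset(panel, subjects = keep), report = report)
}

# mean identity-by-state sharing: 1 - |g_i - g_j| / 2 averaged over SNPs
# observed in both subjects (dist() rescales sums over missing entries)
ibs_matrix <- function(calls) {
  d <- as.matrix(stats::dist(calls, method = "manhattan"))
  1 - d / (2 * ncol(calls))
}

# top principal components of the column-standardized call matrix;
# missing calls are mean-imputed, monomorphic columns dropped
genotype_pca <- function(calls, n_pcs = 10) {
  x <- calls
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  s <- apply(x, 2, stats::sd)
  x <- x[, s > 0, drop = FALSE]
  x <- scale(x)
  k <- min(n_pcs, nrow(x) - 1, ncol(x))
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = k)
  pr$x[, seq_len(k), drop = FALSE]
}

qc_report <- function(axis, steps, n_input, n_survivors, survivors) {
  stopifnot(n_input - sum(steps$removed) == n_survivors)
  structure(list(axis = axis, steps = steps, n_input = n_input,
                 n_survivors = n_survivors, survivors = survivors),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s axis): %d -> %d\n", x$axis, x$n_input,
              x$n_survivors))
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %-14s removed %d\n", x$steps$criterion[i],
                x$steps$removed[i]))
  cat(sprintf("  survivors: %d subjects x %d SNPs\n", x$survivors[1],
              x$survivors[2]))
  invisible(x)
}
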