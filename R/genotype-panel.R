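#' Construct a genotype panel
#'
#' The central container of the package: a subjects x SNPs matrix of biallelic
#' genotype calls together with per-SNP metadata. Calls are stored as integer
#' counts of the second (\code{allele_b}) allele: 0 = homozygous
#' \code{allele_a}, 1 = heterozygous, 2 = homozygous \code{allele_b},
#' \code{NA} = missing. Allele ordering is lexicographic
#' (\code{allele_a < allele_b}); the minor allele is always computed from the
#' observed calls, never stored.
#'
#' @param calls integer matrix, subjects in rows, SNPs in columns; entries in
#'   \code{c(0L, 1L, 2L, NA)}.
#' @param snps data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position}, \code{allele_a}, \code{allele_b}; one row per column of
#'   \code{calls}. Positions are 1-based.
#' @param subjects character vector of subject ids, one per row of
#'   \code{calls}.
#' @return An object of class \code{genotype_panel}: a list with elements
#'   \code{calls}, \code{snps}, \code{subjects}.
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'                 dimnames = list(NULL, NULL))
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chromosome = c("1", "2"),
#'                    position = c(100L, 200L), allele_a = c("A", "C"),
#'                    allele_b = c("G", "T"))
#' gp <- genotype_panel(calls, snps, c("s1", "s2"))
#' @export
genotype_panel <- function(calls, snps, subjects) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  subjects <- as.character(subjects)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  if (nrow(calls) != length(subjects))
    stop("calls has ", nrow(calls), " rows but ", length(subjects),
         " subject ids")
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but ", nrow(snps), " SNP records")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id in panel")
  if (any(!nzchar(snps$snp_id)))
    stop("empty snp_id in panel")
  ok_chrom <- c(as.character(1:22), "X", "Y", "XY", "MT")
  bad <- setdiff(unique(snps$chromosome), ok_chrom)
  if (length(bad))
    stop("invalid chromosome label(s): ", paste(bad, collapse = ", "))
  bad_allele <- !(snps$allele_a %in% c("A", "C", "G", "T")) |
    !(snps$allele_b %in% c("A", "C", "G", "T")) |
    snps$allele_a == snps$allele_b
  if (any(bad_allele))
    stop("invalid alleles at SNP(s): ",
         paste(utils::head(snps$snp_id[bad_allele], 5), collapse = ", "))
  if (!all(is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 2L) stop("calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(subjects, snps$snp_id)
  structure(list(calls = calls, snps = snps, subjects = subjects),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$subjects), "subjects x",
      nrow(x$snps), "SNPs\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  cat("  chromosomes:",
      paste(utils::head(unique(x$snps$chromosome), 8), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Subset a genotype panel by subjects and/or SNPs
#'
#' @param panel a \code{genotype_panel}.
#' @param subjects subject ids or logical/integer index over subjects.
#' @param snps SNP ids or logical/integer index over SNPs.
#' @return the subsetted \code{genotype_panel}.
#' @export
panel_subset <- function(panel, subjects = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- seq_along(panel$subjects)
  vi <- seq_len(nrow(panel$snps))
  if (!is.null(subjects)) {
    si <- if (is.character(subjects)) match(subjects, panel$subjects)
          else si[subjects]
    if (anyNA(si)) stop("unknown subject id(s)")
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, panel$snps$snp_id) else vi[snps]
    if (anyNA(vi)) stop("unknown snp id(s)")
  }
  genotype_panel(panel$calls[si, vi, drop = FALSE],
                 panel$snps[vi, , drop = FALSE],
                 panel$subjects[si])
}

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls. Returns \code{NA} for SNPs with no
#' observed calls.
#'
#' @param panel a \code{genotype_panel}.
#' @return numeric vector, one MAF in [0, 0.5] per SNP.
#' @export
snp_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_obs <- colSums(!is.na(panel$calls))
  b_count <- colSums(panel$calls, na.rm = TRUE)
  p_b <- ifelse(n_obs > 0, b_count / (2 * n_obs), NA_real_)
  pmin(p_b, 1 - p_b)
}

#' Per-SNP genotype call rate
#' @param panel a \code{genotype_panel}.
#' @return numeric vector of fractions in [0, 1].
#' @export
snp_call_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(!is.na(panel$calls))
}

#' Per-subject genotype call rate
#' @param panel a \code{genotype_panel}.
#' @return numeric vector of fractions in [0, 1].
#' @export
subject_call_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  rowMeans(!is.na(panel$calls))
}

#' Per-SNP genotype counts on the minor-allele scale
#'
#' @param panel a \code{genotype_panel}.
#' @return data.frame with columns \code{snp_id}, \code{n_hom_minor},
#'   \code{n_het}, \code{n_hom_major}, \code{n_missing}.
#' @export
genotype_counts <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n0 <- colSums(calls == 0L, na.rm = TRUE)  # hom allele_a
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)  # hom allele_b
  nmiss <- colSums(is.na(calls))
  # minor allele: the rarer of a/b; ties resolved to allele_b
  b_minor <- (2 * n2 + n1) <= (2 * n0 + n1)
  data.frame(snp_id = panel$snps$snp_id,
             n_hom_minor = ifelse(b_minor, n2, n0),
             n_het = n1,
             n_hom_major = ifelse(b_minor, n0, n2),
             n_missing = nmiss,
             stringsAsFactors = FALSE)
}
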