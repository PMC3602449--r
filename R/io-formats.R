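#' Read a genotype panel from PLINK text files (PED/MAP)
#'
#' Parses the classic whitespace-delimited PLINK text dialect. Each PED row
#' carries six leading columns (family id, individual id, father, mother, sex,
#' phenotype) followed by two allele characters per SNP; only the individual
#' id is retained as the subject id. An allele pair of \code{"0 0"} denotes a
#' missing call. For each SNP, \code{allele_a} is the lexicographically
#' smaller of the two alleles observed (or declared); calls are stored as the
#' count of \code{allele_b}.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (columns: chromosome, snp id, genetic
#'   distance, base-pair position; positions 1-based).
#' @return a \code{\link{genotype_panel}}.
#' @export
read_genotype_panel <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"),
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) stop("PED file is empty: ", ped_path)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  subjects <- character(n)
  a1 <- matrix("0", nrow = n, ncol = m)
  a2 <- matrix("0", nrow = n, ncol = m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("PED format error at line ", i, ": expected ", 6 + 2 * m,
           " fields (", m, " SNPs), found ", length(tok))
    subjects[i] <- tok[2]
    g <- tok[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * m, by = 2)]
    a2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2)
      stop("more than 2 alleles at SNP ", map$snp_id[j], ": ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0) obs <- c("A", "C")      # fully missing SNP
    if (length(obs) == 1) {
      # monomorphic: pick any distinct partner so the record stays biallelic
      partner <- setdiff(c("A", "C", "G", "T"), obs)[1]
      obs <- sort(c(obs, partner))
    }
    allele_a[j] <- obs[1]
    allele_b[j] <- obs[2]
    gj <- (a1[, j] == obs[2]) + (a2[, j] == obs[2])
    gj[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    calls[, j] <- gj
  }
  snps <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     position = map$position, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE)
  genotype_panel(calls, snps, subjects)
}

#' Write a genotype panel to PLINK text files (PED/MAP)
#'
#' Inverse of \code{\link{read_genotype_panel}}. The six leading PED columns
#' are written as \code{IID IID 0 0 0 -9}; missing calls become \code{0 0}.
#'
#' @param panel a \code{genotype_panel}.
#' @param ped_path,map_path output paths.
#' @return invisibly, the panel.
#' @export
write_genotype_panel <- function(panel, ped_path, map_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- data.frame(panel$snps$chromosome, panel$snps$snp_id, 0,
                    panel$snps$position)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  m <- nrow(panel$snps)
  n <- length(panel$subjects)
  # allele characters per call code
  out <- file(ped_path, "w")
  on.exit(close(out))
  for (i in seq_len(n)) {
    g <- panel$calls[i, ]
    al1 <- ifelse(is.na(g), "0",
                  ifelse(g >= 1, panel$snps$allele_b, panel$snps$allele_a))
    al2 <- ifelse(is.na(g), "0",
                  ifelse(g == 2, panel$snps$allele_b, panel$snps$allele_a))
    writeLines(paste(c(panel$subjects[i], panel$subjects[i], "0", "0", "0",
                       "-9", as.vector(rbind(al1, al2))), collapse = " "),
               out)
  }
  invisible(panel)
}

#' Write a results table as TSV
#'
#' Tab-separated, with header, stable column order, and floating values
#' rendered with at least 6 significant digits.
#'
#' @param rows data.frame of result records sharing one schema.
#' @param path output path.
#' @return invisibly, \code{rows}.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), NA,
                         formatC(fmt[[j]], digits = 9, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results table to ", path, ": ",
                        conditionMessage(ok))
  invisible(rows)
}

#' Read a results table written by \code{write_results_table}
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Construct a longitudinal phenotype table
#'
#' Long-format spirometry records: one row per subject-visit with the month of
#' the visit and the observed FEV1 in ml.
#'
#' @param subject character vector of subject ids.
#' @param month numeric vector of visit months (non-negative).
#' @param fev1 numeric vector of FEV1 values in ml (positive).
#' @return data.frame of class \code{longitudinal_phenotype}.
#' @export
longitudinal_phenotype <- function(subject, month, fev1) {
  stopifnot(length(subject) == length(month), length(month) == length(fev1))
  if (any(month < 0)) stop("months must be non-negative")
  if (any(fev1 <= 0)) stop("fev1 must be positive (ml)")
  structure(data.frame(subject = as.character(subject), month = month,
                       fev1 = fev1, stringsAsFactors = FALSE),
            class = c("longitudinal_phenotype", "data.frame"))
}

#' Read / write long-format phenotype TSV
#' @param path TSV with columns subject, month, fev1.
#' @return a \code{longitudinal_phenotype}.
#' @export
read_phenotype_long <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  longitudinal_phenotype(d$subject, d$month, d$fev1)
}

#' @rdname read_phenotype_long
#' @param pheno a \code{longitudinal_phenotype}.
#' @export
write_phenotype_long <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pheno)
}

#' Construct a covariate table
#'
#' Per-subject anthropometry plus per-visit endotoxin exposure. The endotoxin
#' covariate used in association models is derived from the visit series (see
#' \code{\link{build_covariate_matrix}}).
#'
#' @param subject character vector of subject ids (unique).
#' @param height numeric, cm.
#' @param age numeric, years.
#' @param fev1_baseline numeric, ml (the observed month-0 measurement).
#' @param endotoxin data.frame with columns \code{subject}, \code{month},
#'   \code{endotoxin} (EU/m3), one row per visit.
#' @return object of class \code{covariate_table}: list with elements
#'   \code{data} (per-subject data.frame) and \code{endotoxin} (long
#'   data.frame).
#' @export
covariate_table <- function(subject, height, age, fev1_baseline, endotoxin) {
  subject <- as.character(subject)
  if (anyDuplicated(subject)) stop("duplicated subject ids")
  stopifnot(length(height) == length(subject),
            length(age) == length(subject),
            length(fev1_baseline) == length(subject))
  if (any(height <= 0) || any(age <= 0) || any(fev1_baseline <= 0))
    stop("covariates must be positive")
  endotoxin <- as.data.frame(endotoxin, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "month", "endotoxin") %in% names(endotoxin)))
  endotoxin$subject <- as.character(endotoxin$subject)
  if (any(endotoxin$endotoxin <= 0)) stop("endotoxin must be positive (EU/m3)")
  structure(list(
    data = data.frame(subject = subject, height = height, age = age,
                      fev1_baseline = fev1_baseline,
                      stringsAsFactors = FALSE),
    endotoxin = endotoxin), class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", nrow(x$data), "subjects,",
      nrow(x$endotoxin), "endotoxin visit records\n")
  invisible(x)
}

#' Read / write covariate tables as TSV
#'
#' @param path TSV with columns subject, height, age, fev1_baseline.
#' @param endotoxin_path TSV with columns subject, month, endotoxin.
#' @return a \code{covariate_table}.
#' @export
read_covariates <- function(path, endotoxin_path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  e <- utils::read.table(endotoxin_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  covariate_table(d$subject, d$height, d$age, d$fev1_baseline, e)
}

#' @rdname read_covariates
#' @param cov a \code{covariate_table}.
#' @export
write_covariates <- function(cov, path, endotoxin_path) {
  utils::write.table(cov$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cov$endotoxin, endotoxin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cov)
}

#' Per-subject endotoxin summary covariate
#'
#' The association models adjust for the average endotoxin exposure on the log
#' scale. Two orders of operations are supported: \code{"log_mean"} (default)
#' takes the natural log of each subject's across-visit mean exposure;
#' \code{"mean_log"} averages the per-visit logs.
#'
#' @param cov a \code{covariate_table}.
#' @param method \code{"log_mean"} or \code{"mean_log"}.
#' @return named numeric vector (subject ids as names).
#' @export
log_endotoxin <- function(cov, method = c("log_mean", "mean_log")) {
  method <- match.arg(method)
  stopifnot(inherits(cov, "covariate_table"))
  e <- cov$endotoxin
  val <- if (method == "log_mean") {
    log(tapply(e$endotoxin, e$subject, mean))
  } else {
    tapply(log(e$endotoxin), e$subject, mean)
  }
  out <- as.numeric(val)[match(cov$data$subject, names(val))]
  names(out) <- cov$data$subject
  out
}
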