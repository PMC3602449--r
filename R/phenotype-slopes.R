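#' Per-subject FEV1 slope by ordinary least squares
#'
#' Fits FEV1 = u0 + es * month by OLS for one subject. The slope \code{es}
#' (ml/month) is the derived phenotype of all downstream association models;
#' \code{u0} is the fitted baseline FEV1.
#'
#' @param months numeric vector of visit months (at least 2 distinct values).
#' @param fev1 numeric vector of FEV1 measurements (ml), same length.
#' @return list of class \code{slope_estimate}: \code{es} (ml/month),
#'   \code{u0} (ml), \code{r2}, \code{n_visits}. \code{r2} is \code{NA} when
#'   both residual and total variance are zero (constant fit through constant
#'   data).
#' @examples
#' estimate_slope(c(0, 18), c(2630, 2450))  # es = -10 ml/month
#' @export
estimate_slope <- function(months, fev1) {
  if (length(months) != length(fev1)) stop("months and fev1 lengths differ")
  if (length(months) < 2) stop("need at least 2 visits")
  if (length(unique(months)) < 2)
    stop("degenerate design: all months identical")
  mx <- mean(months)
  my <- mean(fev1)
  sxx <- sum((months - mx)^2)
  sxy <- sum((months - mx) * (fev1 - my))
  es <- sxy / sxx
  u0 <- my - es * mx
  tss <- sum((fev1 - my)^2)
  rss <- sum((fev1 - u0 - es * months)^2)
  r2 <- if (tss == 0) NA_real_ else max(0, min(1, 1 - rss / tss))
  structure(list(es = es, u0 = u0, r2 = r2, n_visits = length(months)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope_estimate: es = %.3f ml/month, u0 = %.1f ml, R2 = %s, %d visits\n",
              x$es, x$u0,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2), x$n_visits))
  invisible(x)
}

#' Estimate FEV1 slopes for a whole cohort
#'
#' One OLS slope per subject with at least two visits at distinct months;
#' subjects failing that requirement are excluded (and listed), not errored.
#'
#' @param pheno a \code{\link{longitudinal_phenotype}} (or data.frame with
#'   columns subject, month, fev1).
#' @return data.frame of class \code{slope_set} with columns \code{subject},
#'   \code{es}, \code{u0}, \code{r2}, \code{n_visits}; attributes
#'   \code{summary} (mean/sd of es, mean/median r2) and \code{excluded}
#'   (subject ids dropped).
#' @export
estimate_all_slopes <- function(pheno) {
  stopifnot(all(c("subject", "month", "fev1") %in% names(pheno)))
  split_idx <- split(seq_len(nrow(pheno)), pheno$subject)
  ids <- names(split_idx)
  usable <- vapply(split_idx, function(ix)
    length(ix) >= 2 && length(unique(pheno$month[ix])) >= 2, logical(1))
  excluded <- ids[!usable]
  ids <- ids[usable]
  if (length(ids) == 0) stop("no subjects with >= 2 visits at distinct months")
  rows <- lapply(split_idx[ids], function(ix) {
    est <- estimate_slope(pheno$month[ix], pheno$fev1[ix])
    data.frame(es = est$es, u0 = est$u0, r2 = est$r2,
               n_visits = est$n_visits)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(subject = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  smry <- list(n = nrow(out),
               mean_es = mean(out$es),
               sd_es = if (nrow(out) > 1) stats::sd(out$es) else NA_real_,
               mean_r2 = mean(out$r2, na.rm = TRUE),
               median_r2 = stats::median(out$r2, na.rm = TRUE))
  structure(out, summary = smry, excluded = excluded,
            class = c("slope_set", "data.frame"))
}

#' @export
summary.slope_set <- function(object, ...) {
  s <- attr(object, "summary")
  cat(sprintf("%d subjects: mean ES %.2f ml/month (sd %s)\n", s$n, s$mean_es,
              if (is.na(s$sd_es)) "NA" else sprintf("%.2f", s$sd_es)))
  cat(sprintf("per-subject R2: mean %.2f, median %.2f\n", s$mean_r2,
              s$median_r2))
  ex <- attr(object, "excluded")
  if (length(ex))
    cat("excluded (fewer than 2 usable visits):", length(ex), "subject(s)\n")
  invisible(s)
}

#' @export
print.slope_set <- function(x, ...) {
  cat("slope_set with", nrow(x), "subjects\n")
  print.data.frame(utils::head(x, 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
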