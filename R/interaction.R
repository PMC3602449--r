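# small OLS helper shared by the interaction and GRS fits
.ols_fit <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    return(list(ok = FALSE))
  coef <- qr.coef(qx, y)
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  rss <- sum(resid^2)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(rss / df * diag(XtXinv))
  tval <- coef / se
  p <- pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin)
  list(ok = TRUE, coef = coef, se = se, p = p,
       rss = rss, df = df, fitted = as.vector(X %*% coef))
}

# F-test of nested OLS fits with guards for numerically perfect fits:
# a zero RSS improvement is F = 0 (P = 1), a perfect full model over an
# imperfect reduced one is F = Inf (P = 0+)
.nested_f_test <- function(rss0, rss1, d, df1) {
  delta <- rss0 - rss1
  tol <- 1e-8 * max(rss0, 1)
  if (delta <= tol) return(list(f = 0, p = 1))
  if (rss1 <= tol)
    return(list(f = Inf, p = .Machine$double.xmin))
  f <- (delta / d) / (rss1 / df1)
  list(f = f, p = max(stats::pf(f, d, df1, lower.tail = FALSE),
                      .Machine$double.xmin))
}

#' Gene-gene interaction model with joint-cell reporting
#'
#' Fits two equivalent parameterizations of the two-SNP model on the same
#' complete-case set: (i) the product model
#' \code{es ~ covariates + A + B + A:B}, whose A:B coefficient t-test gives
#' the interaction P; and (ii) the joint-cell model with one dummy per
#' non-reference genotype combination (reference = double noncarrier),
#' yielding the per-cell effects reported in interaction tables. Both SNPs
#' must be dominant-coded 0/1.
#'
#' @param es numeric slope vector (ml/month).
#' @param code_a,code_b dominant genotype codes (0/1, NA = missing call).
#' @param covariates numeric covariate matrix, aligned rows.
#' @param labels length-2 character labels for the two factors.
#' @return object of class \code{interaction_result}: list with
#'   \code{factor_a}, \code{factor_b}, \code{cells} (data.frame: level_a,
#'   level_b, n, mean, sd, beta, se, p; the reference cell has NA beta),
#'   \code{interaction_beta}, \code{interaction_p}, \code{n}, \code{q}
#'   (NA until set by a family-wise scan).
#' @export
fit_gene_gene <- function(es, code_a, code_b, covariates,
                          labels = c("A", "B")) {
  covariates <- as.matrix(covariates)
  cc <- !is.na(es) & !is.na(code_a) & !is.na(code_b) &
    stats::complete.cases(covariates)
  y <- es[cc]; a <- code_a[cc]; b <- code_b[cc]
  Z <- covariates[cc, , drop = FALSE]
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("codes must be dominant 0/1")
  n <- length(y)

  lev <- expand.grid(level_a = c(0, 1), level_b = c(0, 1))
  lev <- lev[order(lev$level_a, lev$level_b), ]
  cells <- data.frame(lev,
                      n = NA_integer_, mean = NA_real_, sd = NA_real_,
                      beta = NA_real_, se = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(cells))) {
    inc <- a == cells$level_a[i] & b == cells$level_b[i]
    cells$n[i] <- sum(inc)
    if (any(inc)) cells$mean[i] <- mean(y[inc])
    if (sum(inc) > 1) cells$sd[i] <- stats::sd(y[inc])
  }

  # product model
  prod_fit <- .ols_fit(y, cbind(1, Z, A = a, B = b, AB = a * b))
  int_beta <- int_p <- NA_real_
  if (prod_fit$ok) {
    idx <- ncol(Z) + 4  # intercept + Z + A + B, then AB
    int_beta <- unname(prod_fit$coef[idx])
    int_p <- unname(prod_fit$p[idx])
  }

  # joint-cell model (skipped when a cell is empty)
  if (all(cells$n > 0)) {
    D <- cbind(d01 = as.numeric(a == 0 & b == 1),
               d10 = as.numeric(a == 1 & b == 0),
               d11 = as.numeric(a == 1 & b == 1))
    cell_fit <- .ols_fit(y, cbind(1, Z, D))
    if (cell_fit$ok) {
      pos <- ncol(Z) + 1 + seq_len(3)
      # rows of cells in (0,1), (1,0), (1,1) order after the (0,0) reference
      tgt <- match(c("0:1", "1:0", "1:1"),
                   paste(cells$level_a, cells$level_b, sep = ":"))
      cells$beta[tgt] <- unname(cell_fit$coef[pos])
      cells$se[tgt] <- unname(cell_fit$se[pos])
      cells$p[tgt] <- unname(cell_fit$p[pos])
    }
  }
  structure(list(factor_a = labels[1], factor_b = labels[2], cells = cells,
                 interaction_beta = int_beta, interaction_p = int_p,
                 n = n, q = NA_real_),
            class = "interaction_result")
}

#' Gene-environment interaction model
#'
#' Joint-cell model over the genotype dichotomy crossed with a categorical
#' environment (age band or endotoxin stratum); reference cell = noncarrier
#' at the lowest environment level. The interaction P comes from an F-test
#' comparing the full joint-cell model against the mains-only model
#' (genotype + environment, no product), on (levels - 1) numerator degrees of
#' freedom. The covariate matrix supplied must not contain the covariate the
#' environment was derived from (drop age for age bands, the endotoxin
#' summary for endotoxin strata) to avoid collinearity.
#'
#' @param es numeric slope vector.
#' @param code dominant genotype code (0/1, NA allowed).
#' @param env factor with at least 2 levels, aligned with \code{es}.
#' @param covariates numeric covariate matrix (environment-derived column
#'   removed).
#' @param labels length-2 labels (SNP id, environment name).
#' @return an \code{interaction_result}; \code{cells$level_b} holds the
#'   environment levels.
#' @export
fit_gene_environment <- function(es, code, env, covariates,
                                 labels = c("SNP", "env")) {
  covariates <- as.matrix(covariates)
  env <- droplevels(as.factor(env))
  if (nlevels(env) < 2) stop("environment must have >= 2 levels")
  cc <- !is.na(es) & !is.na(code) & !is.na(env) &
    stats::complete.cases(covariates)
  y <- es[cc]; g <- code[cc]; e <- droplevels(env[cc])
  Z <- covariates[cc, , drop = FALSE]
  if (!all(g %in% c(0, 1))) stop("code must be dominant 0/1")
  L <- nlevels(e)
  n <- length(y)

  lev <- expand.grid(level_a = c(0, 1), level_b = levels(e),
                     stringsAsFactors = FALSE)
  lev <- lev[order(lev$level_a, match(lev$level_b, levels(e))), ]
  cells <- data.frame(lev, n = NA_integer_, mean = NA_real_, sd = NA_real_,
                      beta = NA_real_, se = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(cells))) {
    inc <- g == cells$level_a[i] & e == cells$level_b[i]
    cells$n[i] <- sum(inc)
    if (any(inc)) cells$mean[i] <- mean(y[inc])
    if (sum(inc) > 1) cells$sd[i] <- stats::sd(y[inc])
  }

  Edum <- stats::model.matrix(~ e)[, -1, drop = FALSE]  # L-1 dummies
  int_p <- NA_real_
  # mains-only vs full (mains + product) F-test
  X0 <- cbind(1, Z, g = g, Edum)
  X1 <- cbind(X0, g * Edum)
  f0 <- .ols_fit(y, X0)
  f1 <- .ols_fit(y, X1)
  Fstat <- NA_real_
  if (f0$ok && f1$ok) {
    ft <- .nested_f_test(f0$rss, f1$rss, ncol(X1) - ncol(X0), f1$df)
    Fstat <- ft$f
    int_p <- ft$p
  }

  if (all(cells$n > 0)) {
    key <- paste(g, as.integer(e), sep = ":")
    ref <- "0:1"
    cell_levels <- paste(cells$level_a, match(cells$level_b, levels(e)),
                         sep = ":")
    D <- sapply(setdiff(cell_levels, ref), function(k) as.numeric(key == k))
    cell_fit <- .ols_fit(y, cbind(1, Z, D))
    if (cell_fit$ok) {
      pos <- ncol(Z) + 1 + seq_len(ncol(D))
      tgt <- match(setdiff(cell_levels, ref), cell_levels)
      cells$beta[tgt] <- unname(cell_fit$coef[pos])
      cells$se[tgt] <- unname(cell_fit$se[pos])
      cells$p[tgt] <- unname(cell_fit$p[pos])
    }
  }
  structure(list(factor_a = labels[1], factor_b = labels[2], cells = cells,
                 interaction_beta = NA_real_, interaction_p = int_p,
                 n = n, q = NA_real_, f_stat = Fstat),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction %s x %s: P = %.4g (n = %d%s)\n", x$factor_a,
              x$factor_b, x$interaction_p, x$n,
              if (!is.na(x$q)) sprintf(", FDR q = %.4g", x$q) else ""))
  print.data.frame(x$cells, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Age bands for stratified and interaction analyses
#'
#' Bands <18, [18, 25) and >=25 years (half-open at both interior cuts).
#'
#' @param age numeric, years.
#' @return ordered factor with levels \code{"<18"}, \code{"18-25"},
#'   \code{">=25"}.
#' @export
age_bands <- function(age) {
  cut(age, breaks = c(-Inf, 18, 25, Inf), right = FALSE,
      labels = c("<18", "18-25", ">=25"))
}

#' Endotoxin exposure strata
#'
#' Dichotomizes a per-subject exposure summary at a cutoff (the cohort median
#' by default); ties at the cutoff go to the lower stratum.
#'
#' @param x per-subject exposure (EU/m3).
#' @param cutoff stratum boundary; default \code{median(x)}.
#' @return factor with levels \code{"low"}, \code{"high"}.
#' @export
endotoxin_groups <- function(x, cutoff = stats::median(x, na.rm = TRUE)) {
  factor(ifelse(x <= cutoff, "low", "high"), levels = c("low", "high"))
}

#' All-pairs interaction scan over a set of top SNPs
#'
#' With \code{env = NULL}, fits all C(k,2) gene-gene product/joint-cell
#' models among the given SNPs and attaches Benjamini-Hochberg q-values over
#' the pairwise family. With \code{env = "age"} or \code{"endotoxin"}, fits k
#' gene-environment models (one per SNP) against age bands or
#' median-dichotomized endotoxin, with q-values over that family; the
#' environment-derived covariate is dropped from the adjustment set by
#' default (\code{keep_env_covariate = TRUE} retains it).
#'
#' @inheritParams assoc_scan
#' @param snp_ids character vector of SNP ids (>= 2 for gene-gene).
#' @param env \code{NULL}, \code{"age"} or \code{"endotoxin"}.
#' @param keep_env_covariate keep the environment-derived covariate in the
#'   adjustment set (default FALSE).
#' @return list of class \code{interaction_scan}: \code{fits} (list of
#'   \code{interaction_result} with q set) and \code{table} (data.frame with
#'   factor_a, factor_b, interaction_p, q).
#' @export
pairwise_interaction_scan <- function(panel, slopes, cov, snp_ids,
                                      env = NULL,
                                      endotoxin = c("log_mean", "mean_log"),
                                      keep_env_covariate = FALSE) {
  al <- align_inputs(panel, slopes, cov)
  Zfull <- build_covariate_matrix(cov, endotoxin = endotoxin)
  Z <- Zfull[match(al$subjects, rownames(Zfull)), , drop = FALSE]
  y <- al$es
  sub_panel <- panel_subset(panel, subjects = al$subjects, snps = snp_ids)
  codes <- lapply(seq_along(snp_ids), function(j)
    encode_genotype(sub_panel$calls[, j], "dominant")$code)
  names(codes) <- snp_ids

  fits <- list()
  if (is.null(env)) {
    if (length(snp_ids) < 2) stop("need >= 2 SNPs for gene-gene scan")
    pairs <- utils::combn(snp_ids, 2)
    for (r in seq_len(ncol(pairs))) {
      a <- pairs[1, r]; b <- pairs[2, r]
      fits[[paste(a, b, sep = "_")]] <-
        fit_gene_gene(y, codes[[a]], codes[[b]], Z, labels = c(a, b))
    }
  } else {
    env <- match.arg(env, c("age", "endotoxin"))
    if (env == "age") {
      env_f <- age_bands(Z[, "age"])
      Zi <- if (keep_env_covariate) Z
            else Z[, setdiff(colnames(Z), "age"), drop = FALSE]
    } else {
      e <- cov$endotoxin
      mean_exp <- tapply(e$endotoxin, e$subject, mean)[al$subjects]
      env_f <- endotoxin_groups(as.numeric(mean_exp))
      Zi <- if (keep_env_covariate) Z
            else Z[, setdiff(colnames(Z), "log_endotoxin"), drop = FALSE]
    }
    for (s in snp_ids)
      fits[[paste(s, env, sep = "_")]] <-
        fit_gene_environment(y, codes[[s]], env_f, Zi, labels = c(s, env))
  }
  pvec <- vapply(fits, function(f) f$interaction_p, numeric(1))
  qvec <- rep(NA_real_, length(pvec))
  ok <- !is.na(pvec)
  if (any(ok)) qvec[ok] <- bh_fdr(pvec[ok])
  for (i in seq_along(fits)) fits[[i]]$q <- qvec[i]
  tab <- data.frame(
    factor_a = vapply(fits, function(f) f$factor_a, character(1)),
    factor_b = vapply(fits, function(f) f$factor_b, character(1)),
    interaction_p = pvec, q = qvec, row.names = NULL,
    stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab), class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat("interaction scan:", nrow(x$table), "tests\n")
  tab <- x$table[order(x$table$interaction_p), ]
  print.data.frame(utils::head(tab, 10), row.names = FALSE, digits = 4)
  invisible(x)
}
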