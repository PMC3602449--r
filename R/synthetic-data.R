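#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model the analysis assumes, inverted: per-subject
#' true slopes are a linear function of (dominant-coded) genotype, centered
#' covariates, chosen interactions and Gaussian noise; observed FEV1
#' trajectories are straight lines through the true slope plus within-subject
#' measurement noise; visits follow the cohort's follow-up pattern with
#' monotone dropout.
#'
#' Defaults emulate an endotoxin-exposed occupational cohort: 301 female
#' workers, visits at months 0/3/12/18 with retention matching the 62/42/197
#' follow-up split, a two-component age mixture (young new hires around 18.4
#' years, older transfers around 33.1 years), baseline FEV1 around 2630 ml,
#' and work-area endotoxin levels with cohort median near 163 EU/m3. The
#' within-subject measurement SD (150 ml) is calibrated so that the mean
#' per-subject regression R2 falls in the 0.63-0.73 range; the
#' between-subject slope SD (17 ml/month) makes the overall slope SD about
#' 25 ml/month.
#'
#' @param n_subjects cohort size.
#' @param n_snps number of independent SNPs.
#' @param maf_range minor-allele-frequency range (low, high), in (0, 0.5].
#' @param visit_months strictly increasing visit schedule starting at 0.
#' @param dropout_probs per-visit retention probabilities, conditional on
#'   having attended the previous visit (first element must be 1).
#' @param slope_intercept mean true slope, ml/month.
#' @param covariate_effects named numeric: ml/month per unit of the centered
#'   covariate, names among height, age, fev1_baseline, log_endotoxin.
#' @param snp_effects data.frame with columns \code{snp} (index) and
#'   \code{effect} (ml/month added for dominant carriers).
#' @param interaction_effects list of entries, each a list with \code{type}
#'   ("snp_snp" or "snp_cov"), indices/names \code{a}, \code{b}, and
#'   \code{effect} (ml/month on the product term).
#' @param within_subject_sd FEV1 measurement noise SD, ml.
#' @param between_subject_slope_sd residual slope SD, ml/month.
#' @param baseline_mean_sd length-2 (mean, sd) of baseline FEV1, ml.
#' @param endotoxin_area_levels work-area endotoxin levels, EU/m3; subjects
#'   are assigned to areas uniformly.
#' @param age_mixture list: \code{prop_young}, \code{young} = c(mean, sd),
#'   \code{old} = c(mean, sd) in years.
#' @param height_mean_sd length-2 (mean, sd) of height, cm.
#' @param seed integer seed.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 301, n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       visit_months = c(0, 3, 12, 18),
                       dropout_probs = c(1, 1, 239 / 301, 197 / 239),
                       slope_intercept = -6.79,
                       covariate_effects = c(height = 0, age = 0,
                                             fev1_baseline = 0,
                                             log_endotoxin = 0),
                       snp_effects = NULL,
                       interaction_effects = list(),
                       within_subject_sd = 150,
                       between_subject_slope_sd = 17,
                       baseline_mean_sd = c(2630, 350),
                       endotoxin_area_levels = c(60, 110, 163, 260, 430),
                       age_mixture = list(prop_young = 0.542,
                                          young = c(18.4, 1.2),
                                          old = c(33.1, 5.0)),
                       height_mean_sd = c(160, 5.5),
                       seed = 1) {
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie in (0, 0.5]")
  if (maf_range[1] > maf_range[2]) stop("maf_range must be (low, high)")
  if (visit_months[1] != 0 || any(diff(visit_months) <= 0))
    stop("visit_months must be strictly increasing and start at 0")
  if (length(dropout_probs) != length(visit_months))
    stop("dropout_probs must have one retention probability per visit")
  if (dropout_probs[1] != 1) stop("baseline visit retention must be 1")
  if (any(dropout_probs < 0 | dropout_probs > 1))
    stop("retention probabilities must lie in [0, 1]")
  if (within_subject_sd < 0 || between_subject_slope_sd < 0)
    stop("noise SDs must be non-negative")
  if (!is.null(snp_effects)) {
    snp_effects <- as.data.frame(snp_effects)
    stopifnot(all(c("snp", "effect") %in% names(snp_effects)))
    if (any(snp_effects$snp < 1 | snp_effects$snp > n_snps))
      stop("snp_effects references out-of-range SNP index")
  }
  for (ie in interaction_effects) {
    stopifnot(is.list(ie), ie$type %in% c("snp_snp", "snp_cov"))
    if (ie$type == "snp_snp" &&
        any(c(ie$a, ie$b) < 1 | c(ie$a, ie$b) > n_snps))
      stop("interaction effect references out-of-range SNP index")
    if (ie$type == "snp_cov") {
      if (ie$a < 1 || ie$a > n_snps)
        stop("interaction effect references out-of-range SNP index")
      if (!ie$b %in% c("height", "age", "fev1_baseline", "log_endotoxin"))
        stop("unknown covariate in interaction effect: ", ie$b)
    }
  }
  structure(list(
    n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
    visit_months = visit_months, dropout_probs = dropout_probs,
    slope_intercept = slope_intercept,
    covariate_effects = covariate_effects, snp_effects = snp_effects,
    interaction_effects = interaction_effects,
    within_subject_sd = within_subject_sd,
    between_subject_slope_sd = between_subject_slope_sd,
    baseline_mean_sd = baseline_mean_sd,
    endotoxin_area_levels = endotoxin_area_levels,
    age_mixture = age_mixture, height_mean_sd = height_mean_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate independent SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Genotypes are drawn as Binomial(2, p) minor-allele counts per SNP, i.e.
#' genotype probabilities (1-p)^2, 2p(1-p), p^2 for minor-allele frequency p.
#' \code{allele_b} is the minor allele by construction; SNPs are placed on
#' autosomes 1-22 in rotation.
#'
#' @param n_subjects number of subjects.
#' @param mafs numeric vector of minor-allele frequencies in (0, 0.5], one
#'   per SNP.
#' @param seed integer seed (bit-reproducible output).
#' @return a \code{\link{genotype_panel}}.
#' @export
simulate_genotypes <- function(n_subjects, mafs, seed = 1) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]")
  m <- length(mafs)
  old_seed <- .Random.seed_exists()
  set.seed(seed)
  calls <- vapply(mafs, function(p) stats::rbinom(n_subjects, 2, p),
                  integer(n_subjects))
  old_seed()
  calls <- matrix(as.integer(calls), n_subjects, m)
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chromosome = as.character(rep_len(1:22, m)),
    position = 1000L * seq_len(m),
    allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  genotype_panel(calls, snps, sprintf("subj%04d", seq_len(n_subjects)))
}

#' Duplicate a SNP with optional call flips
#'
#' Appends a copy of an existing SNP's calls, flipping each non-missing call
#' to a random other genotype with the given probability. Useful for
#' producing correlated (linkage-disequilibrium-like) null SNPs when
#' studying min-P behaviour; LD is otherwise not simulated.
#'
#' @param panel a \code{genotype_panel}.
#' @param snp_id SNP to copy.
#' @param new_id id of the copy.
#' @param flip_prob per-call flip probability (0 = perfect copy).
#' @param seed integer seed for the flips.
#' @return the extended \code{genotype_panel}.
#' @export
duplicate_snp <- function(panel, snp_id, new_id, flip_prob = 0, seed = 1) {
  j <- match(snp_id, panel$snps$snp_id)
  if (is.na(j)) stop("SNP not in panel: ", snp_id)
  g <- panel$calls[, j]
  if (flip_prob > 0) {
    old_seed <- .Random.seed_exists()
    set.seed(seed)
    flip <- !is.na(g) & stats::runif(length(g)) < flip_prob
    g[flip] <- (g[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
    old_seed()
  }
  rec <- panel$snps[j, ]
  rec$snp_id <- new_id
  rec$position <- max(panel$snps$position) + 1000L
  genotype_panel(cbind(panel$calls, as.integer(g)),
                 rbind(panel$snps, rec), panel$subjects)
}

#' Simulate a full cohort with known truth
#'
#' Generates genotypes, covariates, true slopes and observed longitudinal
#' FEV1 according to a \code{\link{sim_config}}. The true slope of subject i
#' is
#' \deqn{intercept + \sum_c \gamma_c (x_{ic} - \bar x_c) + \sum_s \delta_s
#'   D_{is} + \sum interactions + N(0, \sigma_b^2)}
#' with dominant codes D and centered covariates x (centering keeps the
#' intercept interpretable as the mean slope). Observed FEV1 at each retained
#' visit is baseline + slope x month + N(0, sigma_w^2). Endotoxin exposure is
#' assigned by work area, with small lognormal visit-to-visit variation.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_cohort} with elements \code{panel}
#'   (\code{genotype_panel}), \code{phenotype}
#'   (\code{longitudinal_phenotype}), \code{covariates}
#'   (\code{covariate_table}), \code{truth} (list with per-subject and
#'   per-SNP truth tables) and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- .Random.seed_exists()
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_snps
  mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  panel <- simulate_genotypes(n, mafs, seed = config$seed + 1L)

  # covariates
  young <- stats::runif(n) < config$age_mixture$prop_young
  age <- ifelse(young,
                stats::rnorm(n, config$age_mixture$young[1],
                             config$age_mixture$young[2]),
                stats::rnorm(n, config$age_mixture$old[1],
                             config$age_mixture$old[2]))
  age <- pmax(age, 16)
  height <- stats::rnorm(n, config$height_mean_sd[1],
                         config$height_mean_sd[2])
  baseline <- pmax(stats::rnorm(n, config$baseline_mean_sd[1],
                                config$baseline_mean_sd[2]), 500)
  area <- sample(seq_along(config$endotoxin_area_levels), n, replace = TRUE)
  level <- config$endotoxin_area_levels[area]
  months <- config$visit_months
  endo <- expand.grid(subject = panel$subjects, month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  endo$endotoxin <- rep(level, length(months)) *
    exp(stats::rnorm(nrow(endo), 0, 0.1))
  mean_exposure <- tapply(endo$endotoxin, endo$subject, mean)
  mean_exposure <- as.numeric(mean_exposure[panel$subjects])

  covar_values <- cbind(height = height, age = age,
                        fev1_baseline = baseline,
                        log_endotoxin = log(mean_exposure))

  # true slope
  slope <- rep(config$slope_intercept, n)
  gamma <- config$covariate_effects
  for (nm in names(gamma)) {
    if (gamma[[nm]] == 0) next
    x <- covar_values[, nm]
    slope <- slope + gamma[[nm]] * (x - mean(x))
  }
  dom <- panel$calls >= 1L
  snp_effect <- numeric(m)
  if (!is.null(config$snp_effects)) {
    snp_effect[config$snp_effects$snp] <- config$snp_effects$effect
    for (r in seq_len(nrow(config$snp_effects)))
      slope <- slope + config$snp_effects$effect[r] *
        dom[, config$snp_effects$snp[r]]
  }
  for (ie in config$interaction_effects) {
    if (ie$type == "snp_snp") {
      slope <- slope + ie$effect * dom[, ie$a] * dom[, ie$b]
    } else {
      x <- covar_values[, ie$b]
      slope <- slope + ie$effect * dom[, ie$a] * (x - mean(x))
    }
  }
  if (config$between_subject_slope_sd > 0)
    slope <- slope + stats::rnorm(n, 0, config$between_subject_slope_sd)

  # visits with monotone dropout
  n_visits <- length(months)
  retained <- matrix(FALSE, n, n_visits)
  retained[, 1] <- TRUE
  for (j in 2:n_visits)
    retained[, j] <- retained[, j - 1] &
      stats::runif(n) < config$dropout_probs[j]

  idx <- which(retained, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  mo <- months[idx[, 2]]
  fev <- baseline[idx[, 1]] + slope[idx[, 1]] * mo
  if (config$within_subject_sd > 0)
    fev <- fev + stats::rnorm(length(fev), 0, config$within_subject_sd)
  fev <- pmax(fev, 1)
  pheno <- longitudinal_phenotype(panel$subjects[idx[, 1]], mo, fev)

  cov <- covariate_table(panel$subjects, height, age, baseline, endo)
  truth <- list(
    subjects = data.frame(subject = panel$subjects, true_slope = slope,
                          height = height, age = age,
                          fev1_baseline = baseline,
                          mean_endotoxin = mean_exposure,
                          n_visits = rowSums(retained),
                          stringsAsFactors = FALSE),
    snps = data.frame(snp_id = panel$snps$snp_id, true_maf = mafs,
                      true_effect = snp_effect, stringsAsFactors = FALSE))
  old_seed()
  structure(list(panel = panel, phenotype = pheno, covariates = cov,
                 truth = truth, config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", x$config$n_subjects, "subjects x", x$config$n_snps,
      "SNPs, seed", x$config$seed, "\n")
  cat("  visits:", paste(x$config$visit_months, collapse = "/"),
      "months;", nrow(x$phenotype), "measurements\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the same formats the readers consume: PED/MAP for the panel, TSV
#' for phenotype, covariates, endotoxin visits and both truth tables, and
#' the configuration as YAML.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.ped", "cohort.map", "phenotype.tsv",
                            "covariates.tsv", "endotoxin.tsv",
                            "truth_subjects.tsv", "truth_snps.tsv",
                            "config.yaml"))
  write_genotype_panel(cohort$panel, paths[1], paths[2])
  write_phenotype_long(cohort$phenotype, paths[3])
  write_covariates(cohort$covariates, paths[4], paths[5])
  utils::write.table(cohort$truth$subjects, paths[6], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$snps, paths[7], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- cohort$config
  cfg$snp_effects <- if (is.null(cfg$snp_effects)) list()
                     else as.list(cfg$snp_effects)
  yaml::write_yaml(unclass(cfg), paths[8], precision = 12L)
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' Reconstructs (and re-validates) a \code{\link{sim_config}} written by
#' \code{\link{write_cohort}}.
#'
#' @param path YAML path.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw$snp_effects))
    raw$snp_effects <- as.data.frame(raw$snp_effects)
  else raw$snp_effects <- NULL
  raw$maf_range <- as.numeric(raw$maf_range)
  raw$visit_months <- as.numeric(raw$visit_months)
  raw$dropout_probs <- as.numeric(raw$dropout_probs)
  raw$covariate_effects <- unlist(raw$covariate_effects)
  raw$baseline_mean_sd <- as.numeric(raw$baseline_mean_sd)
  raw$height_mean_sd <- as.numeric(raw$height_mean_sd)
  raw$endotoxin_area_levels <- as.numeric(raw$endotoxin_area_levels)
  raw$age_mixture <- lapply(raw$age_mixture, as.numeric)
  do.call(sim_config, raw)
}

#' Engineered quality-control fixture panel
#'
#' Builds a panel in which exactly the requested numbers of SNPs and subjects
#' violate each QC criterion when the filters run in the standard order
#' (non-autosomal, SNP call rate, MAF, HWE; subject call rate, relatedness,
#' PCA outliers), and everything else passes with margin. Violation
#' categories are disjoint by construction:
#' \itemize{
#'   \item non-autosomal SNPs are placed on chromosome X;
#'   \item low-call-rate SNPs have 8\% of calls missing (rate 0.92);
#'   \item low-MAF SNPs carry the minor allele at frequency 0.02
#'     (heterozygotes only);
#'   \item HWE-failing SNPs have 25\% minor-allele homozygotes and no
#'     heterozygotes (exact P far below 0.001);
#'   \item all other SNPs sit at Hardy-Weinberg genotype counts with MAF
#'     at least 0.15;
#'   \item the low-call-rate subject has 8\% of its calls missing;
#'   \item each related subject is a copy of a distinct clean subject with
#'     1\% of calls blanked (so the copy, having the lower call rate, is the
#'     member removed);
#'   \item ancestry outliers are drawn with every SNP's allele frequency
#'     flipped, which throws them far out on the top principal component.
#' }
#' Genotype count multisets are deterministic; only their assignment to
#' subjects is shuffled under the seed, so filter outcomes are exact.
#'
#' @param n_subjects,n_snps panel dimensions.
#' @param n_nonautosomal,n_low_callrate,n_low_maf,n_hwe_fail SNP violation
#'   counts (disjoint; must sum to at most \code{n_snps}).
#' @param n_subject_low_callrate,n_related,n_outliers subject violation
#'   counts (disjoint; together with at least \code{max(n_related, 3)} clean
#'   subjects they must fit in \code{n_subjects}).
#' @param seed integer seed.
#' @return a \code{\link{genotype_panel}}.
#' @export
make_qc_fixture <- function(n_subjects, n_snps, n_nonautosomal = 0,
                            n_low_callrate = 0, n_low_maf = 0,
                            n_hwe_fail = 0, n_subject_low_callrate = 0,
                            n_related = 0, n_outliers = 0, seed = 1) {
  snp_bad <- n_nonautosomal + n_low_callrate + n_low_maf + n_hwe_fail
  if (snp_bad > n_snps)
    stop("infeasible: SNP violation counts exceed n_snps")
  subj_bad <- n_subject_low_callrate + n_related + n_outliers
  n_clean <- n_subjects - subj_bad
  if (n_clean < max(n_related, 3))
    stop("infeasible: too few clean subjects for the requested violations")
  # a one-pass z-score rule caps |z| near sqrt(n/k) for k co-located
  # outliers, so they can only exceed 6 SD in a large enough cohort
  if (n_outliers > 0 && n_clean < 40 * n_outliers)
    stop("infeasible: need at least 40 clean subjects per PCA outlier ",
         "for the 6-SD rule to trigger")
  n_base <- n_subjects - n_related - n_outliers  # rows drawn from clean freqs

  old_seed <- .Random.seed_exists()
  on.exit(old_seed())
  set.seed(seed)

  # deterministic genotype-count multisets per category, n = n_base
  hwe_ok <- function(cnt) hwe_exact_test(cnt[3], cnt[2], cnt[1])
  pass_counts <- function(p, n) {
    n2 <- round(n * p^2); n1 <- round(n * 2 * p * (1 - p))
    c(n - n1 - n2, n1, n2)
  }
  p_grid <- seq(0.15, 0.45, by = 0.025)
  pass_pool <- lapply(p_grid, pass_counts, n = n_base)
  ok <- vapply(pass_pool, function(cnt) {
    maf <- (2 * cnt[3] + cnt[2]) / (2 * n_base)
    maf >= 0.10 && hwe_ok(cnt) >= 0.01
  }, logical(1))
  pass_pool <- pass_pool[ok]
  if (!length(pass_pool))
    stop("infeasible: no passing genotype configuration at this n_subjects")
  lowmaf_counts <- {
    n1 <- max(1, round(0.04 * n_base))
    if (n1 / (2 * n_base) >= 0.05)
      stop("infeasible: cannot engineer MAF < 0.05 at this n_subjects")
    c(n_base - n1, n1, 0)
  }
  hwefail_counts <- {
    n2 <- max(1, round(0.25 * n_base))
    cnt <- c(n_base - n2, 0, n2)
    if (hwe_ok(cnt) >= 1e-4)
      stop("infeasible: cannot engineer HWE failure at this n_subjects")
    cnt
  }

  # SNP category assignment (shuffled), then per-SNP genotype columns
  cat_snp <- sample(rep(c("nonauto", "lowcall", "lowmaf", "hwefail", "pass"),
                        c(n_nonautosomal, n_low_callrate, n_low_maf,
                          n_hwe_fail, n_snps - snp_bad)))
  calls <- matrix(NA_integer_, n_subjects, n_snps)
  base_rows <- seq_len(n_base)           # clean + low-call-rate subjects
  p_of <- numeric(n_snps)                # allele_b frequency used per SNP
  n_miss_lowcall <- ceiling(0.08 * n_base)
  for (j in seq_len(n_snps)) {
    cnt <- switch(cat_snp[j],
                  lowmaf = lowmaf_counts,
                  hwefail = hwefail_counts,
                  pass_pool[[1 + (j %% length(pass_pool))]])
    g <- sample(rep(0:2, cnt))
    if (cat_snp[j] == "lowcall")
      g[sample.int(n_base, n_miss_lowcall)] <- NA_integer_
    calls[base_rows, j] <- g
    p_of[j] <- (2 * cnt[3] + cnt[2]) / (2 * n_base)
  }

  # subject roles among the base rows
  roles <- sample(rep(c("lowcall", "clean"),
                      c(n_subject_low_callrate, n_base -
                          n_subject_low_callrate)))
  lowcall_subj <- which(roles == "lowcall")
  clean_subj <- which(roles == "clean")
  for (i in lowcall_subj)
    calls[i, sample.int(n_snps, ceiling(0.08 * n_snps))] <- NA_integer_

  # related pairs: copy of a clean subject with 1% of calls blanked
  rel_rows <- n_base + seq_len(n_related)
  if (n_related > 0) {
    src <- sample(clean_subj, n_related)
    for (r in seq_len(n_related)) {
      g <- calls[src[r], ]
      g[sample.int(n_snps, max(1, ceiling(0.01 * n_snps)))] <- NA_integer_
      calls[rel_rows[r], ] <- g
    }
  }

  # ancestry outliers: allele frequencies flipped at every SNP
  out_rows <- n_base + n_related + seq_len(n_outliers)
  for (i in out_rows)
    calls[i, ] <- stats::rbinom(n_snps, 2, 1 - p_of)

  # shuffle subject order so engineered rows are not contiguous
  perm <- sample.int(n_subjects)
  calls <- calls[perm, , drop = FALSE]

  snps <- data.frame(
    snp_id = sprintf("qc%06d", seq_len(n_snps)),
    chromosome = ifelse(cat_snp == "nonauto", "X",
                        as.character(rep_len(1:22, n_snps))),
    position = 1000L * seq_len(n_snps),
    allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  genotype_panel(calls, snps, sprintf("subj%04d", seq_len(n_subjects)))
}
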