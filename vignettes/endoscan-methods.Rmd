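---
title: "Association scans for the rate of FEV1 decline: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association scans for the rate of FEV1 decline: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoscan)
```

## The two-stage model

`endoscan` implements the classic two-stage ("slope as phenotype") design
for genetic association with longitudinal lung function in an occupational
cohort exposed to endotoxin-laden cotton dust.

**Stage 1.** Each subject's spirometry series is reduced to a single rate:
for subject $i$ with visits at months $t_j$,

$$\mathrm{FEV}_{1,ij} = u_{0i} + ES_i \, t_j + e_{ij},$$

fitted by per-subject ordinary least squares (`estimate_slope`). $ES_i$
(ml/month) is the estimated slope of decline and becomes the phenotype of
every downstream model; $u_{0i}$ is the fitted baseline. Subjects need at
least two visits at distinct months; two-visit subjects are retained by
default even though their fit is saturated ($R^2 = 1$), which inflates the
cohort $R^2$ summary — `summary()` on a slope set reports mean and median
$R^2$ so this is visible.

We deliberately do not use a mixed (random-slope) model: the two-stage
approach keeps every downstream model an ordinary cross-sectional
regression on derived slopes, at a known cost in efficiency.

**Stage 2.** Each SNP is tested in

$$ES_i = \beta_0 + \beta\, G_i + \gamma_1\,\mathrm{height}_i +
\gamma_2\,\mathrm{age}_i + \gamma_3\,\mathrm{FEV}_{1,\mathrm{base},i} +
\gamma_4\,\log \bar E_i + e_i,$$

where $G_i$ is the dominant (0 = major-allele homozygote, 1 = carrier) or
additive (0/1/2 minor-allele count) code and $\bar E_i$ is the subject's
average endotoxin exposure (EU/m³). The reported $\beta$, SE and two-sided
$t$-test P (on $n - k - 2$ df) belong to the genotype term; negative
$\beta$ means carriers decline faster. Under the additive model, SNPs whose
rare-homozygote frequency is ≤ 5% are excluded as statistically fragile.
"FEV1 at baseline" is the observed month-0 measurement, not the fitted
$u_{0i}$: using the fitted intercept would correlate it with $ES_i$ by
construction.

The endotoxin covariate is ambiguous between two orders of operations —
the log of the across-visit mean, or the mean of the per-visit logs. Both
are implemented (`build_covariate_matrix(endotoxin = ...)`); the default is
`"log_mean"` and every scan records the choice in its metadata.

## Quality control

`snp_filter` applies the standard cascade in a fixed order, attributing
each SNP to the first criterion it fails: non-autosomal chromosome, call
rate ≤ 0.95, MAF < 0.05, exact Hardy-Weinberg P < 0.001. The boundary
conventions are deliberately asymmetric (SNPs: remove at *or below* the
call-rate bound; subjects: remove strictly below), and are preserved as
such. MAF and HWE use non-missing calls only, and are not recomputed after
sample filtering — the cascade is single-pass bookkeeping.

The HWE test is the conditional exact test (the genotyping-QC convention),
not the chi-square approximation: given the minor-allele count, all
heterozygote counts of matching parity are enumerated by a numerically
stable recurrence from the conditional mode, and the two-sided P sums the
probabilities of tables no more likely than the one observed. The test
suite checks it against a log-factorial brute-force enumeration for every
genotype table with up to 50 subjects.

`sample_filter` removes, in order: subjects with call rate < 0.95; one
member of each cryptically related pair — mean identity-by-state sharing
above 0.9 is used as a stand-in for a pi-hat screen, removing the
lower-call-rate member (ties: the later subject) — and principal-component
outliers, defined as more than 6 SD from the mean on any of the top 10
components of the standardized genotype matrix (missing calls
mean-imputed). The relatedness and outlier thresholds are conventions, not
published values, and are parameters of `qc_thresholds()`.

One property of the single-pass z-score rule is worth knowing: with $k$
co-located outliers among $n$ subjects, an outlier's own leverage caps its
z-score near $\sqrt{n/k}$, so the 6-SD rule can only fire when
$n \gtrsim 36k$. The fixture generator refuses configurations below
roughly 40 clean subjects per outlier rather than emitting a fixture whose
outliers are undetectable by construction.

## Study-wide error control

Because the chip's gene-centric SNPs are correlated, Bonferroni over the
surviving SNPs (0.05 / 27,611 ≈ 1.81×10⁻⁶ at the published scale) is
conservative. `build_permutation_null` instead calibrates the scan
empirically:

* **Scheme.** Freedman–Lane residual permutation: the phenotype is
  regressed on the covariates once, the residuals are permuted across
  subjects, and the fitted covariate part is added back; the full scan is
  re-run on each permuted phenotype. Genotype columns are never permuted
  independently, so inter-SNP correlation (linkage disequilibrium) is
  preserved — the very reason permutation beats Bonferroni here. A raw
  phenotype shuffle is available (`scheme = "raw"`) for comparison.
* **FWER.** The per-permutation minimum P across SNPs is recorded;
  `fwer_threshold(null, alpha)` returns the lower-tail alpha-quantile of
  that min-P distribution. For independent SNPs this converges to the
  Šidák threshold $1-(1-\alpha)^{1/m}$; for perfectly duplicated SNPs it
  collapses to $\alpha$ (one effective test). Both limits are verified in
  the test suite.
* **FDR.** `permutation_fdr` estimates, for each observed P, the average
  number of null P-values at or below it per permutation divided by the
  number of observed P-values at or below it, capped at 1 and made
  monotone by a cumulative minimum from the largest P downward. No
  $\pi_0$ estimate is applied (it would only tighten the q-values); the
  estimator is therefore slightly conservative.

`n_perm` defaults to 1,000 and values below 100 are refused — tail
quantiles of the min-P distribution are too unstable below that. The null
object stores the pooled sorted null P-values, so memory is
(SNPs × permutations) doubles; at chip scale users should thin either
dimension.

Benjamini–Hochberg q-values (`bh_fdr`, via `stats::p.adjust`) serve the
smaller interaction families, where the permutation machinery would be
overkill.

## Validation and downstream models

**Bootstrap stability** (`bootstrap_stability`): subjects are resampled
with replacement, the per-SNP model refitted, and the proportion of
replicates with P ≤ 0.05/k (k SNPs under validation; e.g. 0.005 for 10) is
reported; ≥ 80% flags the SNP stable. Degenerate replicates — constant
genotype after resampling, rank-deficient designs — count *against*
stability rather than being redrawn, because redrawing would bias the
proportion upward. Slopes are resampled as fixed per-subject quantities;
`refit_slopes = TRUE` re-estimates them inside each replicate from the
visit records, since it is not knowable whether the original analysis did
so.

**Interactions** (`fit_gene_gene`, `fit_gene_environment`): the gene-gene
model is fitted in two algebraically equivalent parameterizations on the
same complete cases — the product model (whose A·B coefficient t-test is
the primary interaction P, matching the single-df P-values such tables
report) and the joint-cell model (reference = double noncarrier) whose
per-cell betas are the table view. Gene-environment models use an F-test
of the genotype-by-level product terms (for a 2-level environment this is
exactly the squared t). Age bands are <18, [18, 25), ≥25 years — the
boundary 25 goes to the upper band; endotoxin is dichotomized at the
cohort median with ties to the lower stratum. By default the
environment-derived covariate is dropped from the adjustment set to avoid
collinearity with its own strata (the alternative — keeping the full
covariate set — is selectable with `keep_env_covariate = TRUE`).

**Genetic risk score** (`derive_risk_coding`, `compute_grs`,
`grs_trend`, `grs_stratified`): the risk side of each top SNP's dominant
dichotomy is read off the sign of its adjusted beta, and the score counts
risk genotypes carried. Missing genotypes contribute 0 (the score is a
lower bound); subjects missing more than 20% of the coded SNPs are
excluded from trend models. The trend model treats the score as a single
ordinal term; a per-score-category parameterization backs coefficient
plots. The coding is derived from the same scan that selected the SNPs —
the winner's-curse circularity is inherent to the design and is
documented rather than corrected. An unweighted count (not beta-weighted)
is used, matching the counted-score convention.

## The simulator as the study's stand-in

No individual-level data accompany the study, so `simulate_cohort`
generates cohorts with the generative structure the analysis assumes,
plus a truth table for parameter-recovery testing. Defaults encode the
study conditions: 301 subjects; visits at months 0/3/12/18 with monotone
retention 1, 1, 239/301, 197/239 (reproducing the 62/42/197 follow-up
split); a two-component age mixture (54.2% young hires ≈ 18.4 y, 45.8%
older transfers ≈ 33.1 y); height ≈ 160 cm; baseline FEV1 ≈ 2630 ml;
work-area endotoxin levels {60, 110, 163, 260, 430} EU/m³ with mild
lognormal visit noise (median area level 163 EU/m³).

Two noise scales are not published and were fixed once, by calibration:

* within-subject FEV1 measurement SD = 150 ml, chosen so the mean
  per-subject $R^2$ of a default cohort lands in the reported 0.63–0.73
  band (a default cohort gives mean 0.65, median 0.72);
* between-subject residual slope SD = 17 ml/month, so the overall slope SD
  is of the order of the reported ≈ 25 ml/month. With 150 ml measurement
  noise the simulated slope SD (≈ 35 ml/month) overshoots that, because
  two-visit subjects carry slope noise of ≈ 70 ml/month; the $R^2$ band
  was treated as the binding calibration target and the slope SD as a
  consequence. Real data evidently have correlated or
  heteroscedastic measurement error this simple model does not capture —
  passing tests show the pipeline's statistics are correct under the
  assumed model, not that the model is a faithful copy of the cohort.

Genotypes are independent SNPs in exact Hardy-Weinberg proportions
(Binomial(2, p) draws); linkage disequilibrium is not simulated by
default. `duplicate_snp` copies a column with a configurable flip
probability, which is how the tests produce totally correlated nulls for
the min-P machinery. Population structure exists only as the engineered
outlier fixture. Effects enter the true slope on dominant codes; covariate
and interaction effects use centered covariates so the intercept remains
the mean slope.

`make_qc_fixture` engineers panels where exactly the requested numbers of
SNPs and subjects violate each QC criterion with margin (violating
categories disjoint): genotype-count multisets are deterministic and only
their assignment to subjects is seeded, so filter outcomes are exact
counts, not probabilistic ones.

## Numerical choices

* All regressions go through QR decompositions (or their
  Frisch–Waugh–Lovell residualized equivalents in the permutation core,
  which are algebraically the same fit); the suite checks them against
  explicit normal-equations oracles at 1e-8 on random instances.
* Rank-deficient or undersized designs yield flagged exclusions, never
  silent drops; the permutation core treats zero-variance residualized
  genotypes the same way.
* Perfect (noise-free) fits would produce P = 0; P-values are floored at
  the smallest positive double so they remain in (0, 1].
* Nested F-tests guard the zero-RSS corner: no improvement → F = 0
  (P = 1); a perfect full model over an imperfect reduced one → P at the
  floor.
* Genotype calls are stored as counts of the lexicographically larger
  allele; the minor allele is always computed from the data (ties at MAF
  0.5 resolve to that allele), never stored.
* Seeds: every stochastic routine takes an explicit seed, restores the
  caller's RNG state afterwards, and reproduces bit-identically.

## Problem sizes in the shipped checks

The packaged tests exercise the published QC scale exactly (49,094 SNPs;
312 subjects) and run the stochastic calibrations at sizes chosen to make
Monte-Carlo bands tight but cheap: 500 global-null cohorts of 150 subjects
× 100 SNPs with 500 permutations each for the FWER/FDR calibration; 2,000
permutations for the Šidák and total-correlation limits; 200 cohort seeds
of 301 subjects for effect-recovery coverage; 500 bootstrap replicates per
stability check. Tolerances on stochastic checks are 3 binomial (or
quantile) standard errors at those sizes, stated next to each assertion.

## Known limitations

* The sample-QC relatedness and outlier rules are reasonable conventions
  (mean-IBS > 0.9; 6 SD on top-10 PCs, one pass), not published
  thresholds; EIGENSTRAT's iterative removal and Tracy–Widom diagnostics
  are out of scope.
* The exact construction of the original permutation procedure is not
  public; the Freedman–Lane reconstruction here preserves the covariate
  structure and LD, and the FWER threshold it yields is data-dependent —
  the published per-SNP threshold (6.29×10⁻⁵) is therefore not a
  reproduction target.
* Imputation, annotation and functional-network analyses that surround
  the published scan are not part of this package; the sex-consistency
  check is not applicable (the cohort design is all-female).
* Sampling covariates and slopes jointly, the bootstrap treats the
  derived slope as data; uncertainty from stage 1 propagates only through
  the slope values themselves.
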