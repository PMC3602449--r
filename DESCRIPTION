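Package: endoscan
Title: Genetic Association Scans for the Rate of Lung-Function Decline in
    Endotoxin-Exposed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-centric association studies of longitudinal
    lung-function decline in occupational cohorts. Estimates per-subject
    monthly FEV1 slopes by ordinary least squares, applies the standard
    genotype and sample quality-control cascade (call rate, minor allele
    frequency, exact Hardy-Weinberg test, relatedness, principal-component
    outliers), runs covariate-adjusted per-SNP linear models under dominant
    and additive coding with genomic-control diagnostics, calibrates
    study-wide family-wise error and false discovery rates by residual
    permutation of the minimum P-value, validates hits by bootstrap
    stability, fits gene-gene and gene-environment interaction models with
    joint-cell reporting, and analyses counted genetic risk scores with
    trend and stratified tests. A seeded cohort simulator with known truth
    supports end-to-end calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
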