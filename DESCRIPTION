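Package: pomskat
Title: Sequence Kernel Association Testing for Ordinal Phenotypes Under the
    Proportional Odds Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Set-based association testing between a group of common genetic
    variants and an ordered categorical phenotype. Fits the proportional odds
    (cumulative logit) model under the null hypothesis of no genetic effect,
    forms a variance-component score statistic with minor-allele-frequency
    based weights, and evaluates its p-value by moment-matching the
    mixture-of-chi-squares null distribution with a Pearson Type III (shifted
    gamma) approximation. Includes per-SNP minimum-p, Bonferroni, principal
    component and joint likelihood-ratio comparator tests, a Gaussian-copula
    genotype simulator with AR(1) linkage disequilibrium, a type I error and
    power simulation harness, and readers for VCF, PLINK .raw and delimited
    dosage matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
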