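Package: pathburden
Title: Pathway-Informed Variant Collapsing for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unweighted minor-allele burden sums and signed pathway gene-set
    scores (the Metabolic Index Score) for candidate-gene case-control
    resequencing studies, with permutation-based inference, max(T)
    family-wise multiple-testing adjustment, linkage-disequilibrium pruning,
    missingness QC and frequency-based imputation, single-variant
    log-additive association with a Firth fallback, and dichotomized odds
    ratios. Ships a seeded case-control genotype simulator that emulates a
    stratified candidate-gene cohort (rarity spectrum, functional classes,
    LD blocks, missingness) with an optional planted signed-score effect,
    so the whole analysis grid can be exercised end-to-end without external
    data. The motivating application is folate/one-carbon pathway variation
    and neural tube defect risk.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
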