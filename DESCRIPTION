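Package: rohburden
Title: Runs-of-Homozygosity Burden Analysis for Multi-Site Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("ROH", "Burden Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls runs of homozygosity (ROH) from hard-call SNP genotypes
    using consecutive-homozygote, density and gap-split rules, computes the
    genomic inbreeding coefficient Froh and its short/long decomposition,
    and fits covariate-adjusted logistic burden regressions of case-control
    status on Froh with dataset fixed effects, ancestry principal components
    from a genomic relationship matrix, missingness and excess
    heterozygosity. Includes sample and SNP quality control (Hardy-Weinberg
    exact test, relatedness, VIF-based LD pruning), a synthetic multi-site
    cohort generator with planted autozygous segments and configurable
    site-level ascertainment confounding, a whole-site label-flip
    permutation null for studying type-I error inflation under site-level
    confounding, and power simulation for the burden test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
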