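Package: feedqtl
Title: Bayesian Window-Variance GWAS for Feed-Efficiency Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping QTL for feedlot feed-efficiency
    traits (average daily gain, dry matter intake, mid-test metabolic body
    weight and residual feed intake) from SNP array genotypes. Implements
    trait derivation from serial weights and daily intakes, animal- and
    marker-level genotype quality control including X-heterozygosity sex
    assignment, BayesB whole-genome regression with a mixture prior on
    marker effects, partitioning of additive genetic variance into
    non-overlapping 1-Mb genome windows, a permutation-derived Johnson Su
    null distribution for window variance shares with Bonferroni-corrected
    QTL calling, and lead-SNP selection by posterior probability of
    inclusion. A half-sib feeding-trial simulator generates LD-structured
    genotypes and correlated traits so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
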