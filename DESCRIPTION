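Package: aimkit
Title: Development and Evaluation of Ancestry-Informative SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating forensic ancestry-informative
    marker (AIM) SNP panels: Rosenberg informativeness for assignment and
    population-specific divergence with cumulative-divergence panel balancing;
    Snipper-style naive-Bayes ancestry classification with Bayes likelihood
    ratios and leave-one-out cross-validation; supervised maximum-likelihood
    (EM) and distance-based (GDA) co-ancestry proportion estimation with
    10-percentile regression comparison, detection summaries and Evanno delta-K;
    pairwise genotype-callset concordance auditing; panel composition audits and
    2-SNP diplotype (microhaplotype) recoding; readers/writers for VCF profiles,
    Snipper training grids and STRUCTURE raw input; and a Balding-Nichols
    synthetic-population generator for end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
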