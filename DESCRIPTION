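Package: medtrans
Title: Identification of Mediated Trans-eQTLs by Multiple-Mediator Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify trans-acting expression quantitative trait loci
    (trans-eQTLs) whose effects are transmitted through the expression of one or
    more nearby (cis) genes. Provides genotype quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, complete-LD deduplication),
    expression normalization, covariate-adjusted cis/trans eQTL scanning with
    Benjamini-Hochberg false discovery control, construction of candidate
    SNP/cis-mediator/trans-gene trios, and percentile-bootstrap hypothesis tests
    of the total mediation effect (TME), the component-wise mediation effects
    (CME), and the single-mediator effect (SME) under a joint multi-mediator
    linear model with correlated mediator errors. Includes a simulation engine
    for type-I error and power studies of the three tests, MAF-matched
    permutation and Fisher exact enrichment tests, and seeded synthetic-fixture
    generators for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
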