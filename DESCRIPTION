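Package: autozyg
Title: Pedigree and Genomic Inbreeding Coefficients for Small Closed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of five inbreeding coefficients for
    small closed livestock populations: the pedigree coefficient F_PED from
    the numerator relationship matrix, the SNP-by-SNP excess-homozygosity
    coefficient F_HOM, the VanRaden method-I genomic-relationship coefficient
    F_GRM, the runs-of-homozygosity coefficient F_ROH from a sliding-window
    scan, and the homozygosity-by-descent coefficient F_HBD from a
    multi-class hidden Markov model with exponential rate classes. Includes
    pedigree and genotype quality control, temporal partitioning of
    autozygosity into age classes, a statistical comparison layer
    (descriptives, normality tests, rank correlations, regressions,
    birth-year trends), and a gene-dropping simulator with exact
    identity-by-descent bookkeeping that supplies ground truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
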