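Package: corLancaster
Title: Correlation-Adjusted Lancaster Combination of Dependent P-Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines p-values from dependent tests with the Lancaster
    (weighted Fisher) procedure. Each p-value is mapped to a chi-square
    variable with a user-chosen weight as its degrees of freedom and the
    variables are summed; under dependence the sum is calibrated by moment
    matching against a scaled chi-square (Satterthwaite) reference, with
    four further tail approximations (Fisher normal, Wilson-Hilferty,
    Cornish-Fisher, Lugannani-Rice saddlepoint). The covariance among the
    transformed values can be supplied or estimated by phenotype
    permutation on raw genotype data. Includes a linkage-disequilibrium
    genotype simulator with logistic disease models for benchmarking
    Type I error and power, and a pathway mode that combines per-gene
    p-values over gene sets (GMT) with Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
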