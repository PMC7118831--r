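Package: afset
Title: Adaptive Fisher Association Tests for SNV Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association testing of single nucleotide variant (SNV)
    sets against binary or continuous traits with the weighted Adaptive Fisher
    (wAF) family of tests: AF, wAF, the directed wAF (wAFd) and a Min-P
    comparator. Marginal score statistics are combined through sorted weighted
    partial sums of -log p-values; the minimum partial-sum p-value is
    calibrated by permutation of trait residuals, with optional covariate
    adjustment and an adaptive step-up permutation budget for genome-wide
    scans. Includes a simulation framework with AR(1)-correlated genotypes for
    type-I error and power studies, plus readers for VCF/matrix genotypes and
    BED gene regions and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
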