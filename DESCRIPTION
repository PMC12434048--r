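Package: vqtlscan
Title: Variance QTL Detection with Parametric and Non-Parametric Dispersion Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects variance quantitative trait loci (vQTLs), variants whose
    genotype groups differ in phenotypic variance, a signature of unmodelled
    gene-environment or gene-gene interaction. Provides five test statistics
    computed on covariate-adjusted residuals (Kruskal-Wallis on median
    deviations, Brown-Forsythe, deviation regression, double generalized
    linear model with optional rank-based inverse-normal transformation, and
    the quantile-integral linear model), a simulation framework for
    calibrating false-positive rate and power under normal, kurtotic and
    skewed error laws, greedy linkage-disequilibrium clumping of scan hits,
    and follow-up direct gene-environment and gene-gene interaction
    regressions with signed -log10(p) matrices. Reads PLINK .bed/.bim/.fam
    hard calls or delimited genotype matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    quantreg
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
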