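Package: rank1de
Title: Dimension-Reduced Differential Expression Analysis Across
    Multiple Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression testing for RNA-seq experiments with
    two or more treatment conditions. Read counts are modelled with a
    negative-binomial two-factor log-linear model in which the
    gene-by-condition interaction is reduced to a rank-one product
    gamma_dg = u_d * v_g, so that each gene is tested with a single
    degree of freedom (Wald chi-squared) regardless of the number of
    conditions. Supports matched (repeated-measures) and unmatched
    designs, four between-lane normalization methods (median, total
    count, upper-quartile, and trimmed mean of M-values), moment and
    shrinkage estimators of the per-gene dispersion, estimation of the
    between-condition correlation of latent expressions from matched
    samples, and a fully seeded simulator of multi-condition counts
    (rank-one, saturated-interaction, and spike-in designs) with
    ROC/FDR evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
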