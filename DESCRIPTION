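Package: factorialDE
Title: Factorial-Treatment Differential Expression and Additivity Analysis
Version: 1.0.0
Authors@R:
    person("Laura", "Mendez", email = "laura.mendez@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 2x2 factorial treatment transcriptome
    experiments (vehicle, two single treatments, and their combination).
    Implements negative-binomial generalized linear model Wald tests with
    median-of-ratios normalization and Benjamini-Hochberg false discovery
    rate control, Venn partitioning of differentially expressed gene sets,
    direction-concordance classification, the expected-additive-effect
    statistic with observed-versus-expected linear regression, attenuation
    quantification for antagonistic combinations, comparative-Ct qPCR
    fold-change computation against multiple housekeeping genes, and a
    negative-binomial count simulator with known per-gene ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
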