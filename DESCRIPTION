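Package: lctgsa
Title: Linear Combination Tests for Gene Set Analysis of Continuous Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Self-contained gene set analysis for continuous phenotypes.
    Implements the linear combination test (LCT) and a regression-function
    variant (LCT2), both built on a Schafer-Strimmer shrinkage estimate of the
    gene expression covariance matrix and an orthogonal transform that makes
    permutation testing cheap, together with two comparator statistics (a
    continuous-phenotype SAM-GS and a Global Test score statistic). Includes a
    simulation framework for type-I-error and power studies under structured
    gene-gene correlation, a multi-gene-set screening pipeline with Storey
    q-values, and readers and writers for tab-delimited expression matrices and
    GMT gene set catalogs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
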