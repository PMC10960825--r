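Package: modulomics
Title: Consensus Multi-Omic Module Discovery for Case-Control Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers disease-associated multi-omic modules from paired
    microbiome feature tables (taxa, pathways, metabolites) and a binary
    phenotype. Sparse generalized canonical correlation analysis with the
    phenotype encoded as an extra single-feature block is fitted repeatedly
    on data subsamples; features that persistently share sparse components
    form a co-occurrence network whose connected components are consensus
    modules. Each module is summarised by its first principal component and
    retained only if it predicts the phenotype (AUC) and couples omics
    (cross-omic Spearman correlation) better than size-matched random
    feature sets. Includes shared preprocessing for compositional and
    metabolite data, an early-integration random-forest baseline with
    shadow-feature selection and permutation-based importance p-values,
    cross-study module overlap tests, and a synthetic multi-omic generator
    with planted modules for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
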