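Package: dysbiosr
Title: Dysbiosis Index Scoring with a Normobiotic PCA Reference Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gut-microbiome dysbiosis by fitting a principal-component
    ("normobiotic") reference model on healthy-control abundance profiles and
    scoring samples with Hotelling's T-squared and Q (squared prediction error)
    statistics against their confidence limits, combined into a Dysbiosis Index.
    Includes the surrounding analysis stages: compositional preprocessing
    (relative abundance, CLR, minimum-value imputation, log2 z-scores, Pareto
    scaling), Kruskal-Wallis and Dunn post-hoc group comparison with Bonferroni
    or Benjamini-Hochberg adjustment, LDA-effect-size discovery of discriminatory
    taxa, Spearman correlation networks between taxa and metabolites, and a
    synthetic four-arm trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
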