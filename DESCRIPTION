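Package: robustpheno
Title: Performance and Robustness Analysis of Microbial Phenotypes Across
    Perturbation Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the robustness of microbial strains from microtiter
    cultivation data. Extracts five growth phenotypes (maximum specific growth
    rate, lag phase, final cell dry weight, biomass yield, ethanol yield) from
    plate-reader growth curves and endpoint assays, applies theoretical-bound
    trimming and quantile outlier flagging, computes a mean-normalized Fano
    factor robustness statistic per strain and phenotype over a perturbation
    space, measures the influence of each perturbation group on robustness,
    detects performance-robustness trade-offs by rank correlation, and scores
    the improvement in growth rate after a culture transfer. A synthetic-data
    generator with known ground truth (including an embeddable rank correlation
    between performance and robustness) makes every stage testable without
    cultivation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
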