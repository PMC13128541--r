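Package: rhizonet
Title: Co-Occurrence Network Stability and Core Taxa for Plant Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds signed microbial co-occurrence networks from zOTU count
    tables (Spearman correlation with false-discovery-rate control), and
    quantifies their stability with natural connectivity, robustness under
    random node removal, community cohesion, average variation degree (AVD)
    and vulnerability. Classifies node topological roles with the
    within-module degree z-score and participation coefficient (Zi-Pi),
    identifies habitat specialists from specificity-occupancy profiles, and
    screens core taxa as the intersection of shared, specialist and keystone
    zOTUs. Includes a multi-kingdom synthetic community generator with
    planted correlation structure so every stage of the pipeline can be
    validated against known ground truth, plus nearest-taxon-index (NTI)
    computation for community phylogenetic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    knitr,
    picante,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
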