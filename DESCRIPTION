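Package: konet
Title: Community-Wide Metabolic Networks from Multi-Omic KO Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates metagenomic and metatranscriptomic per-gene read
    counts into KEGG-orthology (KO) level gene-copy and transcript
    abundances and relative gene expression, reconstructs community-wide
    metabolic networks in which KO groups are nodes and shared substrate or
    product metabolites are undirected edges, computes topological load
    scores (betweenness centrality normalised by node degree and total edge
    count) and choke points, and selects genes encoding key community
    functionalities as nodes falling in the top percentiles of both load
    score and relative expression. Includes pathway over-representation and
    paired seasonal betweenness comparisons, a synthetic multi-omics
    generator with planted keystone genes for validation, and a pipeline
    orchestrator with TSV/GraphML interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
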