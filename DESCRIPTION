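Package: tkiprio
Title: Rank-Aggregation Prioritization of Drug-Resistance Genes from
    Paired Expression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes genes associated with acquired drug resistance by
    scoring each gene's differential expression between paired sensitive and
    resistant samples in each of K experiments, ranking genes per experiment,
    and fusing the K rankings with a discounted rating system into a single
    prioritization. Top candidates are characterized by hypergeometric gene-set
    over-representation with Benjamini-Hochberg false discovery rate control
    and an enrichment-map overlap graph. Includes a synthetic-study generator
    with planted resistance genes for end-to-end recovery testing, readers and
    writers for expression TSV, GMT, and GraphML formats, qPCR delta-Ct
    relative-expression and two-group Welch t utilities, and a reproducible
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
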