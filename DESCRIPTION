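Package: netbarcode
Title: Persistent Barcodes and Topological Inference for Weighted Complete Networks
Version: 0.1.0
Authors@R:
    person("netbarcode", "developers", email = "netbarcode@example.org",
           role = c("aut", "cre"))
Description: Topological data analysis of dense weighted networks such as
    functional brain connectivity matrices. Implements the birth-death
    decomposition of graph filtrations (every edge weight is either the
    birth of a connected component or the death of a cycle), Betti curves,
    expected persistent barcodes of random complete graphs via
    order-statistic quantile approximations, confidence bands on birth and
    death values, and group-level inference with the expected topological
    loss (ETL), maximum-gap and area-under-Betti-curve statistics using
    permutation and Wilcoxon rank-sum tests. Includes random-network
    generators and simulation drivers for power and size studies, plus
    readers for adjacency matrices, edge lists and region time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
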