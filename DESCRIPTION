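Package: spacergraphs
Title: Compressed Spacer Graphs for CRISPR Array Diversity in Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes the diversity and dynamics of CRISPR arrays
    captured in long sequencing reads. Clusters spacer sequences at an
    identity threshold so near-identical spacers share a label, groups
    spacer-sharing arrays with a greedy reference-based algorithm, builds
    directed spacer graphs and compresses non-branching chains into blocks,
    infers array orientation from repeat degeneracy and graph topology,
    summarizes trailer-end ("anchor") spacer conservation and dataset-level
    spacer redundancy, and matches spacers back against same-sample reads
    to flag candidate protospacers outside predicted CRISPR regions. A
    forward simulator of CRISPR array evolution (leader-end spacer gains,
    segmental losses, point mutations, read fragmentation) provides ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
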