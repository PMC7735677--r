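Package: causalpaths
Title: Reasoning over Signed Causal Paths in Multimodal Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts activatory and inhibitory causal paths of bounded length
    between source and target nodes of a signed directed biological network,
    and turns the resulting relative-effect scores into prioritized lists of
    single drugs, multi-target drugs, and drug combinations predicted to
    reverse (or induce) diseases and phenotypes. Implements a memoized
    dynamic-programming walk counter and a pruned simple-path counter,
    consistency-based prioritization criteria over a range of maximum path
    lengths, a degree- and sign-preserving edge-swap permutation null model,
    and a synthetic multimodal network generator with planted drug-disease
    mechanisms for end-to-end testing. Networks are read and written in
    GraphML, node-link JSON, and tab-separated edge-list formats.
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
    pROC,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
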