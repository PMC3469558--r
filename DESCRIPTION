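Package: hbdest
Title: Hybrid Alignment-Free Distance for EST Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clusters expressed sequence tags (ESTs) with a hybrid
    alignment-free distance that combines a windowed word-count (d2)
    distance, capturing local subsequence similarity, with a bounded
    relative-entropy distance over whole-sequence k-mer frequencies,
    capturing global sequence composition. Includes density-based
    (DBSCAN-style) and single-linkage clustering from the resulting
    distance matrix, external validation by the Jaccard index against
    a reference partition, a gene-family EST simulator with ground
    truth for benchmarking, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
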