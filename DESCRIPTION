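Package: afclust
Title: Alignment-Free Sequence Clustering with Adaptive Similarity Cut-Offs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters nucleotide or protein sequences without a global
    identity threshold. Pairwise similarities are estimated from bottom-s
    MinHash sketches of k-mers (Mash distances) and fed into a complete
    weighted graph that is clustered iteratively: Leiden community detection
    under the Constant Potts Model proposes raw clusters at a decreasing
    resolution, a binning rule derives a per-cluster adaptive cut-off from
    cluster separation and intra-cluster similarity, and graph contraction
    carries validated clusters into the next iteration. Includes
    alignment-based cluster evaluation reports, external and internal
    validation indices (NMI, purity, silhouette), and a generator of
    labelled synthetic homologous sequence families for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
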