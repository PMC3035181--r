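Package: fastconsensus
Title: Consensus Clustering and Its Fast Approximation for Estimating the
    Number of Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stability-based estimation of the number of clusters in an
    expression matrix by consensus (subsampling) clustering. Repeatedly
    subsamples the items, clusters each subsample, and summarises the
    pairwise co-clustering frequencies in a per-k consensus matrix; the
    empirical CDF of the consensus entries, its area A(k) and the
    proportional area increase Delta(k) yield a plateau-based prediction
    of the cluster number k*. Includes the fast variant FC, which reorders
    the resampling and cluster-number loops so that a single dendrogram
    per subsample serves every k, with bit-identical results to the naive
    computation. Hierarchical (average, complete, single linkage) and
    k-means engines, synthetic benchmark generators with known gold k,
    TSV/JSON input and output, and a command-line driver are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
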