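Package: dmnph
Title: Persistent Homology Analysis of Resting-State Brain Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional connectivity networks from region-of-interest
    BOLD time series using the 1 - Pearson dissimilarity, runs the zeroth-homology
    graph filtration whose filtration values are the minimum-spanning-tree weights,
    and derives persistent network features (Betti number plot slope, integrated
    persistent feature slope) alongside standard graph-theoretic measures
    (characteristic path length, global efficiency, network radius, modularity,
    eigenvector centrality). Includes two-group permutation inference over subject
    features and a synthetic cohort generator with planted group effects for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
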