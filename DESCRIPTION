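Package: semnetkit
Title: Construction, Analysis and Growth Modeling of Semantic Networks
Version: 0.1.0
Authors@R: person("semnetkit", "developers", role = c("aut", "cre"),
    email = "semnetkit@example.org")
Description: Tools for building semantic networks from distributional semantic
    models and free-association norms, and for characterizing their structure.
    Builds sparse word-document and windowed word-word co-occurrence matrices,
    applies log-entropy tf-idf and positive pointwise mutual information (ppmi)
    weighting, smooths by truncated singular value decomposition, and derives
    directed networks by the k-nearest-neighbor rule or by a cumulative cosine
    similarity threshold. Network descriptors include small-world statistics
    against uniform random baselines and the hierarchical scaling of the local
    clustering coefficient C(k) ~ k^-beta. Degree distributions are fitted by
    discrete maximum likelihood for power-law, truncated power-law and
    exponential families with Kolmogorov-Smirnov lower-bound selection,
    semi-parametric bootstrap goodness of fit and 10-fold cross-validated model
    selection. A growing-network simulator mixes preferential attachment
    (semantic differentiation) with uniform random attachment (experiential
    correlation), with Barabasi-Albert and mixed-attachment baselines, and a
    synthetic-corpus generator provides controlled paradigmatic and syntagmatic
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
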