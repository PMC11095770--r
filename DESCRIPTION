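Package: hypernull
Title: Degree-Constrained Tripartite Hypergraph Null Models and Aggregation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding, constructing and sampling simple tripartite
    3-uniform hypergraphs with prescribed degree sequences.  Provides a
    polynomial-time constructor for third almost-regular degree sequences
    (bipartite multigraph realization, column balancing, bipartite
    Havel-Hakimi realization of the shadow sequence, and lifting), an
    energy-based Metropolis chain over all hypergraphs on fixed vertex
    classes whose moves are switches, hinge flips and toggles, and a
    Parallel Tempering sampler with a quartile-matched temperature ladder
    that draws approximately uniform realizations of a target degree
    sequence.  The samples drive a hypergraph-based exact chi-squared
    aggregation test, alongside the classical theoretical chi-squared test
    and a fixed-margin (generalized hypergeometric) exact test on
    contingency tables.  Exhaustive enumeration oracles at desk scale and
    synthetic triplet-table generators support validation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
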