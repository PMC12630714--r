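Package: urbiso
Title: Urban Isolation and the Geography of Political Violence
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how politically motivated violence relates to
    city size and geographical isolation. Implements gravity-model flow
    centrality on highway networks (a flow-weighted betweenness), degree
    based isolation classes, distance-threshold assignment of conflict
    events to their nearest city, urban-scaling exponent estimation on
    log-log city data, and lethality-ratio statistics with event
    subsampling robustness checks. Ships a synthetic city-system generator
    with planted scaling exponents and isolation effects for end-to-end
    validation of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
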