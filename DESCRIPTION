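Package: rrspace
Title: Representative Random Sampling of Chemical Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to define a chemical space from element/valence rules,
    enumerate all feasible sum formulas by nested integer partitions,
    count or estimate the number of distinct molecular multigraphs
    (protomolecules) per formula using exact enumeration, a small-world
    average-path-length relation and asymptotic degree-sequence counting,
    and draw approximately uniform random molecules across the space with
    a degree-preserving edge-swap Markov chain.  Also scores how
    representative an existing molecule database is of its underlying
    chemical space using Kolmogorov-Smirnov and Kullback-Leibler
    statistics over stoichiometry distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
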