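Package: mrbm
Title: Multivalued Refinement of Boolean Models via Partial Most Permissive
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for qualitative logical models of regulatory networks:
    parsing BoolNet-style Boolean models, deriving signed regulatory graphs,
    building explicit state transition graphs under the asynchronous, most
    permissive, and partial most permissive updating schemes, computing fixed
    points, attractors, reachability and basins of attraction, constructing
    multivalued refinements through per-clause regulation thresholds, and
    searching for minimal sets of components whose most-permissive updating
    recovers a fixed-point reachability that the asynchronous dynamics misses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
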