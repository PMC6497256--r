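Package: bncontrol
Title: Exact Control of Synchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solver for the finite-horizon control problem on synchronous
    Boolean networks: given a gene regulatory network with designated external
    (control) nodes, an initial state, a desired state and a horizon, find a
    sequence of external-node assignments that drives the network into the
    desired state, or prove that none exists. The solver decomposes the wiring
    diagram into strongly connected components, fills forward per-node
    reachability tables for easy components, runs an embedded backward dynamic
    program inside multi-node components, and backtracks recursively over
    dependent components. A full-network backward dynamic program and a
    brute-force enumerator are included as baselines and cross-checks, together
    with published regulatory-network fixtures (Drosophila melanogaster
    segment-polarity subnetwork, T-cell receptor state table) and a seeded
    random-instance generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
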