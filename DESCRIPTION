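Package: rtip
Title: Roto-Translationally Invariant Potential Pathway Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-pathway sampling driven by a roto-translationally
    invariant potential (RTIP) built from pristine Cartesian coordinates.
    Provides quaternion least-squares rigid-body superposition with all four
    alignment modes, a degeneracy-smoothed Gaussian attractive bias with
    analytic gradients, toy reactive pair potentials with scan-verifiable
    barriers, a biased-relaxation sampling driver with climb/drop termination
    thresholds, distance-based bond perception with canonical molecular-graph
    keys, and reaction-network analysis (minimax bottleneck routes and
    energetic-span effective barriers over free-energy profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
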