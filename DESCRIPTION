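Package: ndc80link
Title: Stiffness Time-Tracing and Elastic Models of the Ndc80-Microtubule Link
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Time-traces the effective stiffness of kinetochore
    Ndc80-microtubule attachments from optical-trap bead-position
    recordings using interval-wise equipartition estimates, and models the
    link with structure-based elastic elements: a half-space-confined
    two-bond freely jointed chain for the Ndc80 complex, the entropic
    worm-like-chain stiffness of the microtubule, an elastica model of
    flaring protofilaments with spontaneous curvature, and a two-state
    extended freely jointed chain for the PEG tether.  Elements compose in
    series and parallel with a force-dependent attachment number (catch-
    bond envelope), stiffness-force relations are characterised by robust
    Huber-loss power-law fits, and a seeded overdamped-Langevin simulator
    of the trap experiment validates the estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
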