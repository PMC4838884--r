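Package: endonet
Title: Attractor Landscape Analysis of Endogenous Molecular-Cellular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling closed ("endogenous") molecular-cellular
    regulatory networks as dynamical systems. Signed activation/inhibition
    networks are compiled into normalized Hill-type ordinary differential
    equations and Boolean update dynamics; fixed points are enumerated from
    random initial conditions with Newton refinement, classified by Jacobian
    spectrum into attractors, saddles and other unstable points, and linked
    into a saddle-mediated transition graph. Clamp-and-release perturbation
    protocols simulate induced switching between attractors (for example
    differentiation-therapy style interventions), and random-parameter
    resampling quantifies attractor robustness. Includes generators for
    synthetic fixture networks with brute-force-verifiable attractor
    structure and for noisy discretized expression call tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
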