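Package: iceprop
Title: Stochastic Simulation of Intracellular Ice Formation and Propagation
    in Small Tissue Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lattice-free agent-based simulation of intracellular ice
    formation (IIF) and intercellular ice propagation during the freezing of
    small tissue constructs such as hepatocyte disc monolayers, spheroids and
    tissue slabs.  Couples a Mazur-type water-transport model of cell
    dehydration under linear cooling with diffusion-limited intracellular
    nucleation kinetics, a non-dimensional time transform, exact
    continuous-time Markov chain solutions on symmetry-reduced state spaces,
    fixed-step and Gillespie Monte Carlo samplers of ice propagation on
    arbitrary contact graphs, and center-based cell mechanics with
    water-to-ice volume expansion and detachment (fissure) detection.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
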