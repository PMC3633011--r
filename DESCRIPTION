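Package: oncolevel
Title: Multi-Level Petri-Net and Population Modelling of Oncoantigen-Driven
    Vaccination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and analysing multi-level models of tumour
    growth in which a Petri-net representation of a proliferation signalling
    network (ErbB-family receptors, PI3K/Akt, mTOR and TLR2 cascades)
    parameterises a cancer stem cell / progenitor / terminal cell population
    model. Provides Petri-net construction and firing semantics, minimal
    P-semiflow (conservation law) computation by exact integer Farkas
    elimination, reachability-graph construction with CTL model checking,
    automatic derivation of generalized mass-action ODE systems from
    rate-bound nets with semiflow-based model reduction, a Gillespie
    stochastic simulator, the nine-compartment CSC/PC/TC population ODE
    system, coupling of molecular trajectories (cyclin D, NF-kB, BAD) into
    time-varying proliferation rates, and in-silico growth-factor injection
    and vaccination experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
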