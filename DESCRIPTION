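Package: stehkin
Title: Branched Kinetic Modelling of Epoxide Hydrolase Catalysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pre-steady-state and steady-state analysis of the
    branched kinetic mechanism of potato epoxide hydrolase (StEH1) and
    related alpha/beta-hydrolase-fold enzymes. Simulates the two-branch
    alkylenzyme reaction scheme as a stiff ODE system, fits single and
    double exponentials with floating endpoints to stopped-flow
    fluorescence traces, selects fit order by F-test, regresses observed
    rates against substrate concentration to extract microscopic rate
    constants (k2, K_S, k-2, k3, k5+k-5) with delta-method standard
    errors, interconverts rate constants and Eyring activation free
    energies, and predicts branch flux, regioselectivity and enantiomeric
    excess from barrier sets or rate sets. Includes a synthetic-data
    generator for noisy averaged stopped-flow traces, observed-rate
    series and Michaelis-Menten initial-rate tables, plus fixtures of
    published StEH1 variant rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
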