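Package: biofilmhedge
Title: Biofilm-Plankton Allocation Dynamics, Fitness Landscapes, and
    Bet-Hedging Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the life-history trade-off between
    fast-growing planktonic cells and stress-resistant biofilm cells in
    patchy environments. Provides closed-form and numerical solutions of
    coupled biofilm-plankton population dynamics within an ephemeral
    patch, per-founder reproductive-number fitness over the planktonic
    colonization rate with regime classification (pure plankton, mixed,
    pure biofilm), stochastic environment sampling with variance
    treatments, serial-passaging simulations quantifying bet-hedging via
    variance, arithmetic-mean and geometric-mean fitness, and a minimal
    lattice simulator of frontier-limited biofilm growth geometry.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
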