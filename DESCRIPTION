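Package: usystem
Title: Structure-Based Power-Law (U-System) Models of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs Generalized Mass Action (GMA) power-law ordinary
    differential equation models of metabolic reaction networks directly from
    pathway topology, using the Unity-system (U-system) convention: all rate
    constants 1, substrate kinetic orders 1, and kinetic orders of -0.5 and
    +0.5 for inhibitory and activating regulation.  Provides stiff/non-stiff
    integration of the resulting systems, steady-state location by damped
    Newton iteration in log-concentration space, Monte-Carlo parameter
    ensembles with stability filtering and envelope statistics, single
    parameter and branch-point rate-constant sweeps, in-silico knockdowns,
    metabolite supplementation via Fick's-law diffusion uptake, and
    correlation-based scoring of simulations against replicated metabolite
    time-series data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
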