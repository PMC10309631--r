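Package: lingslide
Title: Bilingual Language Competition Dynamics with Threshold-Triggered
    Sliding-Mode Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the planar compartmental model of two competing
    languages with a bilingual group: population proportions evolve on the
    2-simplex under status- and interaction-weighted transfer rates with an
    attractiveness exponent. Provides the reduction to a four-coefficient
    planar system, closed-form trivial and interior equilibria, Jacobian
    based stability classification via the trace-determinant (p-q) plane,
    positive-invariance boundary checks, error-controlled trajectory
    integration, and a Filippov piecewise-smooth extension in which a
    policy parameter switch below an endangerment threshold creates a
    sliding segment and a pseudo-equilibrium representing stable language
    coexistence. Includes nullcline and direction-field export, a registry
    of worked scenarios, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
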