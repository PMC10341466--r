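Package: fraudgame
Title: Tripartite Evolutionary Game Analysis of Healthcare Fraud Supervision
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the supervision of healthcare fraud as a
    three-player evolutionary game between a hospital (compliant vs illegal
    operation), a third-party investigator (true vs false investigation) and a
    local government (strict supervision vs non-supervision) under a
    reward-punishment mechanism.  Implements the 16-parameter payoff model, the
    replicator dynamics on the unit cube, equilibrium enumeration and Jacobian
    eigenvalue stability classification (first Lyapunov method), indifference
    thresholds with region measures and sensitivity signs, deterministic ODE
    simulation of scenario presets, and single-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
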