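Package: sonarPCoD
Title: Individual-Based Bioenergetic Modelling of Beaked Whale Populations
    Exposed to Navy Sonar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the population consequences of disturbance (PCoD) from
    mid-frequency active sonar (MFAS) for beaked whale populations resident
    around instrumented Navy ranges (Cuvier's beaked whale at SOAR, Blainville's
    beaked whale at AUTEC). Individuals move among discrete habitat areas
    according to a continuous-time Markov model, feed on a shared
    self-replenishing prey base with area-specific prey encounter rates, and
    grow, reproduce and die under a dynamic energy budget. Hourly sonar records
    are converted to relative foraging-activity reductions via a dose-response
    curve and run-length encoded into disturbance events that either suppress
    foraging for an Erlang-distributed period, displace whales off range, or
    both. Includes synthetic sonar-schedule generators, replicate experiment
    runners, prey-productivity calibration, and life-history and recovery
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
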