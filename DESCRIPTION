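Package: t2dsim
Title: Discrete-Event Microsimulation of Type 2 Diabetes Burden
Version: 0.1.0
Authors@R:
    person("T2D", "Simulation Team", email = "t2dsim@example.org", role = c("aut", "cre"))
Description: Individual-level discrete-event state-transition microsimulation
    for forecasting type 2 diabetes incidence, prevalence and disability-adjusted
    life years (DALYs) in a heterogeneous national population. Includes synthetic
    population generation from marginal tables, calibration of net annual
    risk-factor transition probabilities from age-smoothed prevalence curves,
    FINDRISC-based incidence, relative-risk-adjusted mortality, slope and
    relative indices of inequality, intraclass-correlation agreement checks,
    and probabilistic sensitivity analysis with percentile uncertainty intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
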