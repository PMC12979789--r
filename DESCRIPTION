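Package: metascope
Title: Aerobic-Scope Analysis of Fitness Thresholds in Juvenile Salmon
Version: 0.1.0
Authors@R:
    person("Delta", "Ecophysiology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking aerobic scope to ecological fitness in
    river-rearing and migrating fishes. Estimates Arrhenius metabolic traits
    (hypoxia-tolerance intercept A and temperature sensitivity E) from
    SMR/MMR respirometry via critical oxygen tension, converts environmental
    monitoring data (temperature, dissolved oxygen, salinity) to oxygen
    partial pressure and the metabolic index (factorial aerobic scope
    realized in the environment), fits binomial smooth models of binary
    fitness outcomes with random intercepts, detects ecological thresholds
    (phi_crit, phi_stable) by two-breakpoint segmented regression on
    log-odds prediction curves, models predation probability from tethered
    prey deployments, and provides seeded synthetic-data generators
    emulating all input streams for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    splines,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
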