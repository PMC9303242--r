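Package: signalbalance
Title: Balance Model of Honest Sexual Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing honest sexual signaling as a constrained
    resource-allocation problem. Fitness components (e.g. mating success and
    viability) are represented as functions of investment with analytic
    derivatives; the package finds globally optimal allocations of a fixed
    resource budget under additive or multiplicative fitness, traces optimal
    allocations across budgets (including corner solutions and
    discontinuities), classifies signaling as honest or dishonest from the
    monotonicity of optimal signal investment in the budget, and computes the
    fitness-set geometry (phenotype sets, isoclines, optimal loci) used to
    visualise such trade-offs. Includes a catalog of worked example scenarios
    and a seeded random-scenario generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
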