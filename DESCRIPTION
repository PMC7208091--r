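Package: pollenalloc
Title: Sex Allocation, Pollen Density, and Fertilization Success in Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic model of generative reproduction in plant
    populations under a limited gametic resource budget. Ovule and pollen
    numbers follow from a linear resource trade-off, retained pollen
    disperses uniformly over a bounded range partitioned into
    pollen-catching-surface units, and an ovule is fertilized when at
    least one pollen settles on its unit, giving a binomial occupancy
    probability for the expected proportion and number of fertilized
    ovules. The package locates the optimal sexual allocation by solving
    its implicit optimality equation, finds the dual allocations that
    achieve a common fertilization level, evaluates the three strategies
    that can compensate a sudden resource decline (re-allocation, raising
    pollen retention, shrinking the dispersal range) together with their
    feasibility conditions, and validates the closed forms against a
    Monte Carlo balls-in-bins dispersal simulator. Includes parameter
    sweeps, figure data tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
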