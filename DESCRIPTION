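Package: tetradkit
Title: Tetrad Analysis of Meiotic Crossing Over and Crossover Interference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for budding-yeast tetrad genetics: classification of
    four-spore tetrads into parental ditype, tetratype and nonparental ditype
    classes; genetic map distances by the Perkins formula with delta-method
    standard errors; single-spore recombination frequencies with exact
    binomial confidence intervals; crossover-interference statistics for
    adjacent interval pairs (Malkova partition ratio with G-test significance,
    coefficient of coincidence); statistics for spore-autonomous fluorescence
    crossover assays (tetratype fractions, Fisher/chi-square tests,
    Benjamini-Hochberg multiplicity control, wild-type/null/intermediate
    phenotype calls); and a meiosis simulator with tunable crossover
    interference (stationary gamma renewal model), a non-interfering
    crossover fraction, no chromatid interference, and optional spore
    inviability and meiosis-I nondisjunction, together with closed-form
    oracles for expected tetrad-class frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
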