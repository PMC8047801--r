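Package: mgff
Title: Magnesium Force-Field Parametrization and Solution-Property Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parametrizing divalent magnesium ions in classical
    biomolecular force fields and for analysing the solution properties that
    drive the parametrization. Implements Lennard-Jones 12-6 and 12-6-4
    pair-potential algebra with standard and scaled Lorentz-Berthelot
    combination rules, hydration-shell structure analysis from radial
    distribution functions, a transition-counting estimator of the
    water-exchange rate constant with block-averaged errors and a
    transition-state-theory upper bound, Kirkwood-Buff activity-coefficient
    derivatives for 2:1 electrolytes, standard-state ion-binding
    thermodynamics from one-dimensional free-energy profiles, and the
    three-step grid-search selection workflow that combines these
    observables. Ships synthetic-data generators with closed-form ground
    truths so every analysis stage can be validated at desk scale, plus
    readers and writers for two-column XVG-style tables, plain-text
    trajectories, and GROMACS topology-include snippets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
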