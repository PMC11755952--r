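Package: epiwait
Title: Cost-Effectiveness of Watchful Waiting After Epinephrine Autoinjector Use
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-cycle Markov cohort model comparing watchful waiting at home
    against immediate emergency-department transfer after epinephrine
    autoinjector use for severe food-allergic reactions in Canadian children.
    Provides the full parameter set (probabilities, 2022 CAD costs, utilities)
    with their derivation arithmetic, a seven-state cohort engine with a
    microsimulation oracle, reward accrual with discounting under healthcare
    and societal perspectives, and the base-case, one-way deterministic
    sensitivity, probabilistic sensitivity (cost-effectiveness plane and
    acceptability curve), and scenario analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
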