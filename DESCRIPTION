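Package: twowaymin
Title: Two-Way Minimization and Comparator Randomization Schemes for Small Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate-adaptive treatment allocation for small two-arm clinical
    trials.  Implements two-way minimization, an adaptive scheme that for each
    new subject stochastically chooses -- with a probability that grows
    geometrically with the arm-size imbalance -- between minimizing the
    imbalance in the total numbers of subjects and minimizing a weighted
    distributional imbalance of the prognostic factors across arms.  Also
    provides five comparator schemes (simple randomization, permuted blocks,
    stratified permuted blocks, deterministic and biased-coin Pocock-Simon
    minimization), a sequential real-time allocation mode with resumable JSON
    trial state, a synthetic-trial simulator with normal responses and
    regression-adjusted treatment-effect analysis, and a Monte-Carlo evaluation
    engine reporting bias, variance, type I error, power and two allocation
    predictability indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
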