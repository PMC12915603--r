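Package: marginalmajority
Title: Marginal Majority Effects and Lock-In in Sequential Binary Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lock-in in sequential binary choice under
    social influence. Represents influence curves (urn functions) mapping an
    option's current popularity to its choice probability, decomposes them
    into a continuous part and a marginal majority jump at popularity 1/2,
    classifies equilibria (diagonal downcrossings), and evaluates the
    marginal-majority lock-in criterion M > d together with a closed-form
    lower bound on the lock-in probability derived from the survival
    probability of a biased random walk. Includes a seeded generalized-urn
    simulator (with a party-signal variant), estimators of the marginal
    majority effect and the inherent appeal difference from multiple-world
    sequential-choice data, aggregate inference via Poisson-binomial
    simulation, logistic and Nadaraya-Watson regression of lock-in on model
    quantities, and a synthetic-experiment generator emulating published
    multiple-world study designs.
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
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
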