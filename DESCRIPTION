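Package: riskbout
Title: Risk-Sensitive Novel-Object Exploration via Bayes-Adaptive MDPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the intermittent, risk-sensitive exploration of a novel
    object by individual mice as a Bayes-adaptive Markov decision process.
    An agent holds a Bayesian noisy-or belief over a monotone hazard of
    (imagined) predator detection, harvests a depletable and regenerating
    exploration-bonus pool at the object, and plans by receding-horizon tree
    search under a nested conditional value at risk (nCVaR) objective.
    Simulated state trajectories are parsed into approach bouts and
    behavioural phases, summarised into group-specific statistic vectors
    (brave, intermediate, timid phenotypes), and fitted to minute-resolution
    bout records by approximate Bayesian computation with sequential Monte
    Carlo (ABC-SMC). Includes a synthetic-data generator for boxcar-shaped
    phase profiles and a reproducible pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
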