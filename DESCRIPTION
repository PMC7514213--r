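Package: sensegain
Title: Fitness Value of Individually Sensed Information in Growing Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much fitness a population of growing,
    phenotype-switching organisms gains from individually sensed environmental
    information, compared with a signal shared by the whole population. Provides
    a discrete-time population model over finite environment, signal and
    phenotype state spaces; exact transfer-matrix calculators for path-ensemble
    fitness and retrospective (selection-biased) path distributions;
    information measures (fitness gain, allocation fidelity, directed
    information, Bayesian-inference loss); closed-form Bayes-optimal switching
    and metabolic-allocation strategies; and exact plus Monte Carlo
    verification of the detailed, integral and average fluctuation relations
    these quantities satisfy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
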