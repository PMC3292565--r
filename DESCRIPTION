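Package: trapaware
Title: Trap-Dependent Capture-Recapture Models via Trap-Awareness States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Open-population capture-recapture models with an immediate trap
    response on capture, formulated as a hidden Markov model over
    trap-awareness states (trap aware / trap unaware / dead) and, in the
    multistate version, over awareness crossed with two states of interest.
    Provides exact conditional likelihoods by the forward algorithm,
    maximum-likelihood fitting on the logit scale with Wald intervals and
    identifiability diagnostics, the traditional split-capture-history
    formulation of trap dependence and the naive Cormack-Jolly-Seber model
    for comparison, the Test 2.CT contingency diagnostic for short-term
    trap dependence, an exact simulator with transients and losses on
    capture, and readers and writers for MARK '.inp' and CSV encounter
    history formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
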