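Package: frmodule
Title: Comparative Functional-Response Analysis for Community-Module Predation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative predator functional-response analysis in
    multi-factor community-module experiments: phenomenological response-type
    classification by polynomial logistic regression with an AIC fallback,
    mechanistic maximum-likelihood fitting of the Rogers random-predator
    (prey-depletion) equation via the Lambert W function with indicator-variable
    treatment coding and interaction contrasts, nonparametric bootstrap
    confidence envelopes for fitted response curves, Kruskal-Wallis analysis of
    partial prey consumption, and a synthetic-data generator that emulates a
    fully factorial predator x parasitism x higher-order-predator x density
    design with controls, replicate-exclusion rules and quality-control
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
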