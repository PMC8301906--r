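Package: orthosim
Title: Sequential Learning of Shallow and Deep Orthographies in a
    Delta-Rule Decoding Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates sequential acquisition of two alphabetic
    orthographies of different spelling-sound consistency with a two-layer
    linear associative network trained by the delta rule, including
    cross-orthography weight transfer (seeding a second-language decoding
    network from a trained first-language network), a cycles-to-threshold
    naming-latency readout, and weight-usage analyses.  Provides generators
    for artificial shallow and deep orthographies, Zipfian lexicons and
    word/pseudo-word stimulus sets, plus a reaction-time analysis pipeline
    for naming-latency experiments: staged trial exclusion, log transform,
    first-orthography advantage scores, summary-statistic t tests,
    rank-based comparisons, and random-intercept mixed models with a
    planned difference-of-differences contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
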