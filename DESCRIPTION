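Package: agreesim
Title: Simulating Subject-Verb Agreement Attraction with Recurrent Neural Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying subject-verb agreement attraction with
    word-level recurrent neural language models. Generates synthetic training
    corpora from a number-marked probabilistic grammar (with CCG-style
    supertags for a multi-task objective), trains simple recurrent and LSTM
    language models with an optional jointly weighted supertagging decoder,
    links next-word probability distributions to behavioral measures
    (surprisal for reading-time paradigms; one-sample, max-prob, and n-sample
    completion probabilities for production paradigms), runs six classic
    agreement-attraction experimental designs, analyzes the resulting effects
    with beta and linear mixed-effects regression, and probes trained
    representations via per-unit ablation and single-step nullspace
    ("amnesic") projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmmTMB,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
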