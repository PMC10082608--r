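Package: grnsemble
Title: Gene Regulatory Network Inference with Shapley-Value Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from steady-state
    expression data. For every target gene the expression is regressed on
    candidate transcription factors with a random-forest and an
    extremely-randomized-trees ensemble, and each regulator is scored by the
    mean absolute Shapley value of its expression across samples; a third
    score accumulates absolute linear support-vector-regression coefficients
    over repeated row subsamples, with the SVR cost and tolerance tuned per
    target by Bayesian optimization. The three scores are min-max normalized,
    combined by a weighted average, z-scored, and emitted as a ranked directed
    edge list. Includes readers and writers for the tab-separated expression /
    transcription-factor / gold-standard formats used by the DREAM network
    inference challenges, ROC and precision-recall evaluation against a gold
    standard, a linear-Gaussian synthetic network and expression simulator for
    self-contained benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    e1071,
    lhs,
    jsonlite,
    Rcpp,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
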