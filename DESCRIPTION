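Package: actiongram
Title: Action-Grammar Extraction from Behavioral Event Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the structural complexity of symbolic behavioral
    event sequences (ethograms). Fits multinomial hidden Markov models with
    multi-restart Baum-Welch EM and selects model order by information
    criteria; extracts superordinate "states-of-states" structure by fitting
    a second HMM to decoded state paths; induces deterministic context-free
    grammars with the k-Sequitur algorithm and computes compression,
    rule-hierarchy and entropy statistics; and derives per-sequence
    complexity covariates suitable as parametric regressors in neuroimaging
    analyses. Includes synthetic-corpus generators emulating simple
    (flake-removal) and complex (platform-preparation) tool-making action
    sequences, and a command-line interface.
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
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
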