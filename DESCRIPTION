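Package: seqprof
Title: De Novo Protein Sequence Profiles from a Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates position-specific scoring matrices (PSSMs) for protein
    sequences de novo, without iterative database search, using a word-embedded
    LSTM network trained to imitate teacher profiles. Includes parsing of
    HMM-profile match-state emissions into PSSMs, a lossless ASCII PSSM dialect
    alongside a PSI-BLAST-style display block, truncated-memory (context reset)
    prediction for probing how much sequence context the network uses, a
    synthetic context-dependent teacher with a long-range pairing mode for
    controlled experiments, and superfamily-weighted ROC / partial-AUC
    evaluation of ranked homology hit lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
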