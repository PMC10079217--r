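Package: dispcomm
Title: Experimental Evolution of Displaced Communication in Sender-Receiver Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates experimental evolution of displaced communication between
    pairs of foraging agents on a one-dimensional circular world. Sender and
    receiver agents are controlled by fixed-topology continuous-time recurrent
    neural networks (CTRNNs) whose parameters evolve under a genetic algorithm
    with tournament selection. The package implements the full generational
    loop with communication, no-communication and constrained-sender
    treatments, counterfactual probe manipulations of evolved populations
    (fixed amplitude, mean-amplitude replay, onset shift, duration lock), and
    the analysis layer: food-found classification, success histograms,
    between-trial signal-variation statistics, onset-delay extraction,
    evolutionary milestones, and nonparametric treatment comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
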