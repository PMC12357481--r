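Package: trapsim
Title: Forward Simulation of Transposable Element Invasions Under the
    piRNA Cluster Trap Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulator of transposable element (TE)
    invasions in diploid populations under the piRNA cluster trap model, in
    which a TE proliferates until one copy inserts into a piRNA cluster and
    silences all copies in trans. Each insertion carries an integer insertion
    bias in [-100, 100] controlling its probability of landing inside a
    cluster. The package simulates discrete non-overlapping generations with
    fecundity selection, per-chromosome recombination and biased
    transposition, tracks the rapid, shotgun and inactive invasion phases,
    and ships drivers for establishment probability, invasion summaries,
    cluster-size by bias fitness sweeps, and pairwise competition between
    TEs of different biases. Results are tidy tibbles with broom-style
    tidy()/glance() and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
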