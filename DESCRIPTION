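Package: improvtp
Title: Spectro-Temporal Transition-Probability Analysis of Improvised Melodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying implicit statistical structure in symbolic
    (MIDI or note-list) recordings of improvised music. A polyphonic piece is
    reduced to its skyline melody, re-encoded into relative pitch-interval and
    inter-onset-interval-ratio n-grams at Markov orders 1-6 across four
    spectro-temporal sequence types, and summarised as transition-probability
    tables, information content and conditional entropy. Downstream analyses
    compare musicians' corpora: principal component analysis of per-piece
    transition-probability vectors, mixed-design ANOVA on logit-transformed
    probabilities, and collinearity-gated stepwise regressions of chronological
    order on probabilities or entropies. A seeded synthetic-corpus generator
    with known Markov ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
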