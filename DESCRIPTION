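Package: moralnet
Title: Moral Foundations Scoring and Moral Homophily on Retweet Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dictionary-based moral-foundations analysis of short social-media
    texts and the social networks they induce. Parses LIWC-format moral
    foundations dictionaries (word and word-stem entries), computes per-tweet
    moral-loading vectors over the five foundations (Care, Fairness, Ingroup,
    Authority, Purity), aggregates them into per-user moral profiles with
    exclusion rules, builds weighted undirected retweet networks over labeled
    users, and measures per-node and per-foundation moral homophily with a
    label-permutation null model. Also provides valence classification of
    tweets stratified by foundation, corpus-level comparisons (Kruskal-Wallis
    tests and principal component analysis of loading vectors), and a
    synthetic-data generator (lexicons, corpora, planted-homophily networks)
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
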