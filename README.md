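# moralnet

Dictionary-based moral-foundations analysis of short social-media texts
and of the retweet networks they induce.

`moralnet` is for computational social scientists and moral-psychology
researchers who want to (1) score tweets against a moral foundations
dictionary, (2) derive per-user moral profiles, (3) measure whether
users preferentially retweet others who share their dominant moral
foundation, and (4) compare moral expression and emotional valence
across corpora (e.g. across languages). Every stage also runs on
synthetic data with known ground truth, so the whole pipeline is
testable without any external download.

## The statistics at its core

**Tweet moral loading.** Against a LIWC-format dictionary mapping words
and prefix stems to foundation × polarity categories (Care, Fairness,
Ingroup, Authority, Purity; virtue and vice pooled), a tweet *t* gets

    ml_j(t) = (# token occurrences matching foundation j) /
              (# token occurrences matching any of the five foundations)

General-morality categories are excluded; tweets with no foundation
match are filtered. The tweet's label is the argmax set (ties allowed).

**User profiles.** mp_ij = share of user i's moral tweets labeled j.
The user's label is the unique argmax; users with a tied argmax or
fewer than two moral tweets are `EXCLUDED`.

**Moral homophily.** On the weighted undirected retweet network over
labeled users (edge weight = retweet events between a pair),

    h_i = (weight of i's same-label edges) / (weight of all i's edges)
    H_j = mean of h_i over nodes labeled j

with a label-permutation null model supplying the calibrated baseline
for each H_j, and k-core extraction for display export (GEXF / TSV).

**Corpus comparison.** Per-dimension Kruskal–Wallis rank tests (tie
corrected) and covariance PCA of the per-tweet loading vectors; with a
foundation-disjoint dictionary the vectors live on a 4-simplex, so
exactly four components carry variance.

See the methods vignette (`vignettes/moralnet-methods.Rmd`) for the
model, conventions and design choices.

## Worked example

A small illustrative dictionary ships with the package (a synthetic
stand-in with the real dictionaries' category structure; real analyses
should use a full moral foundations dictionary in the same `.dic`
format):

```r
library(moralnet)

lex <- parse_liwc_dic(system.file("extdata", "synthetic_mfd.dic",
                                  package = "moralnet"))
corpus <- tibble::tibble(
  tweet_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
  user_id  = c("ann", "ann", "ann", "bob", "bob", "cat"),
  text = c("Killing is #immoral and cruel",
           "we must protect the weak and be kind",
           "loyal to my family, always",
           "cheating the system is so unfair",
           "dishonest leaders cheat us all",
           "just had lunch http://t.co/x"),
  retweet_of_user = c(NA, NA, "bob", "ann", NA, NA)
)

labeled <- filter_moral_corpus(corpus, lex)
#> 1 of 6 tweets had no moral-dictionary match and were filtered
labeled[, c("tweet_id", "ml_care", "ml_fairness", "ml_ingroup", "labels")]
#>   tweet_id ml_care ml_fairness ml_ingroup labels
#> 1 t1             1           0          0 CARE
#> 2 t2             1           0          0 CARE
#> 3 t3             0           0          1 INGROUP
#> 4 t4             0           1          0 FAIRNESS
#> 5 t5             0           1          0 FAIRNESS
```

t6 ("just had lunch") carries no moral vocabulary and is dropped; t1's
"killing" and "cruel" both match Care-vice stems, so its Care loading
is 2/2 = 1.

```r
profiles <- build_user_profiles(labeled)
profiles[, c("user_id", "mp_care", "mp_ingroup", "n_moral_tweets", "label")]
#>   user_id mp_care mp_ingroup n_moral_tweets label
#> 1 ann       0.667      0.333              3 CARE
#> 2 bob       0          0                  2 FAIRNESS
```

cat had one moral tweet only — below the two-tweet floor — and ann's
dominant foundation is Care (2 of 3 moral tweets). The two retweet
events (t3, t4) both connect ann and bob, giving one edge of weight 2:

```r
net <- build_retweet_network(corpus, profiles)
net
#> <retweet_network> 2 nodes, 1 edges
network_homophily(net)$per_foundation
#>   foundation     H n_nodes homophilous
#> 1 CARE           0       1 FALSE
#> 2 FAIRNESS       0       1 FALSE
```

ann's only edge goes to a Fairness-labeled user, so her homophily —
and therefore Care's network score — is 0. On corpora of realistic
size, `permutation_null()` supplies the baseline each `H` should be
judged against.

For an end-to-end run (scoring → profiles → network → valence →
comparison) from one configuration, see `run_pipeline()`; a thin
command-line wrapper lives at `inst/scripts/moralnet.R`.

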