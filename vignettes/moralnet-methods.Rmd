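---
title: "Methods: dictionary-based moral scoring and moral homophily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-based moral scoring and moral homophily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralnet)
```

## The model

Moral Foundations Theory describes moral judgement along five dimensions —
Care, Fairness, Ingroup (loyalty), Authority and Purity — each with a
virtue and a vice pole. `moralnet` measures how these foundations are
expressed in short social-media texts and whether users cluster by them
when they retweet each other.

### Tweet-level moral loading

A moral foundations dictionary in LIWC `.dic` format maps words and
prefix stems (`killer*`) to foundation-by-polarity categories. For a
tokenized tweet $t_i$, the loading on foundation $j$ is

$$ml_{ij} = \frac{|W_{d_j}(t_i)|}{|W(t_i)|},$$

where $W_{d_j}(t_i)$ are the tweet's token occurrences matching any
category (virtue or vice pooled) of foundation $j$ and $W(t_i)$ are the
occurrences matching any of the five foundations. General-morality
dictionary categories are excluded from both numerator and denominator:
the denominator is defined over the five foundations only, so a tweet
containing nothing but generic morality words has an undefined loading
and is filtered, exactly like a tweet with no dictionary match at all.

Two counting conventions are defensible because the definition above
speaks of "sets of words": counting token *occurrences* (a multiset, so a
repeated moral word weighs more) or counting distinct *types*. We default
to occurrences — the standard LIWC convention — and expose
`count = "types"` throughout for sensitivity analysis.

A tweet's label is the full argmax set of its loading vector; a tie
yields a multi-labeled tweet. Ties are detected on the integer numerators
(all five share one denominator), never on floating-point ratios.

### User profiles

A user's profile is the share of their moral tweets labeled with each
foundation: $mp_{ij} = |Tu_{ij}| / |Tu_i|$. A multi-labeled tweet counts
once in each labeled subset $Tu_{ij}$ but once in the total $Tu_i$, so
the five shares can sum to more than 1. The user's own label is the
foundation of maximum share; a tied maximum, or fewer than two moral
tweets, marks the user `EXCLUDED` — the tie rule removes users whose
dominant foundation is ambiguous, and the two-tweet floor removes
labelings supported by a single observation. Retweeted posts count
toward the retweeting user's profile by default (`include_retweets`
disables this): a user's retweets are part of their expressed moral
attention.

### Retweet-network homophily

The retweet network is **undirected**: an edge joins two labeled users
when either retweeted the other, weighted by the number of retweet
events between the pair, in either direction. Direction is discarded
because the quantity of interest is association, not information flow;
reciprocal retweets accumulate on one weight. Self-retweets are dropped
at ingest. Nodes are exactly the endpoints of retained edges, so every
node has at least one incident edge and per-node homophily is always
defined.

For node $i$ with label $D_i$, the homophily is the weighted same-label
edge fraction

$$h_i = \frac{\sum_{e(i,j):\,D_j = D_i} w_{ij}}{\sum_{e(i,j)} w_{ij}},$$

and the per-foundation score $H_j$ is the unweighted mean of $h_i$ over
nodes labeled $j$. The denominator runs over *all* of $i$'s incident
edges, including cross-label ones — with a same-label-only denominator
$h_i$ would be identically 1. Foundations with no labeled nodes are
reported absent, not zero.

A conventional reading calls a foundation homophilous when $H_j > 0.5$;
we report that flag but do not build logic on it, because the neutral
baseline for $H_j$ is not 0.5 — under random mixing it is roughly the
foundation's label share among network neighbours. `permutation_null()`
makes that baseline explicit: it shuffles node labels uniformly over the
fixed graph and returns the null distribution of each $H_j$. Comparing
an observed score to its null mean (in units of the null standard
deviation) is the calibrated judgement; the 0.5 flag is kept for
comparability with common practice.

`k_core()` extracts the maximal subnetwork of unweighted degree at least
k by iterative pruning (via igraph's coreness), the usual thinning step
before visual export; `write_gexf()` and `write_edgelist_tsv()` emit the
formats external layout tools consume. We deliberately do not render
figures — plotting layout is the caller's concern.

### Valence

Emotional valence scores live in $[-1, 1]$; the class thresholds are
strict signs (positive $> 0$, negative $< 0$, neutral exactly 0). The
packaged default scorer is a transparent lexicon mean — the average
polarity of matched tokens, 0 when none match. External sentiment tools
(VADER for English, oseti for Japanese) honour the same contract and
plug in as a one-function `scorer` argument; their grammatical rules are
out of scope here, so conclusions drawn with the default scorer are
about the pipeline, not about those tools. Valence is computed on the
pre-processed tokens by default (configurable by supplying raw text and
a custom scorer). Per-foundation stratification counts a multi-labeled
tweet under each of its labels, mirroring the profile convention, and
each foundation's three percentages sum to 100.

### Corpus comparison

Per-dimension two-group comparisons use the Kruskal–Wallis rank test
(via `stats::kruskal.test`) with tie correction — loadings are heavily
tied since many tweets share simple fractions — referred to a
chi-square on 1 degree of freedom. Zero loadings are included by
default (dimension j compares all moral tweets of corpus A vs B);
`labeled_only = TRUE` restricts to tweets labeled j.

PCA (via `stats::prcomp`) operates on the per-tweet loading vectors of a
corpus. The default is covariance PCA without standardization: all five
variables share the $[0, 1]$ scale, and with a foundation-disjoint
lexicon every defined loading vector sums to exactly 1, so the data lie
on a 4-simplex and exactly four components carry variance — the fifth is
the simplex normal. Components with variance below $10^{-12}$ are
reported as zero-variance; loadings are unit-norm, and an
`absolute_loadings` mode returns the magnitudes used for contribution
heatmaps.

## The synthetic-data generator

Because the pipeline's statistical behaviour must be checkable without
any external download, `generate_lexicon()`, `generate_corpus()` and
`generate_retweet_network()` produce inputs with known ground truth.

* **Lexicons** follow the standard category layout (five foundations ×
  virtue/vice plus one general category). Vocabularies are
  foundation-disjoint by construction — each category uses a distinct
  fixed prefix of equal length, so no stem of one foundation can match a
  word of another — which makes expected loadings analytic. The
  background vocabulary is disjoint from the moral one for the same
  reason.
* **Corpora** draw, per user, a tweet count, per tweet a token count,
  and per token a Bernoulli moral/background choice; moral tokens draw
  their foundation i.i.d. from the user's mixture and then a uniform
  word from that foundation's vocabulary. Defaults emulate the shape of
  a keyword-collected moral-discussion corpus: a skewed (geometric,
  mean 3) tweets-per-user distribution reflecting that the vast
  majority of users post at most a handful of times; short token lists
  (geometric, mean 8, roughly a preprocessed tweet); a moral token rate
  of 0.2 (keyword-collected tweets are morality-adjacent, but most
  tokens are ordinary vocabulary); and a retweet rate of 0.3. These are
  choices of plausible magnitude, not estimates of any particular
  dataset.
* **Networks** plant homophily directly: labels drawn from a 5-simplex,
  each unordered pair joined with probability `p_same` (matching
  labels) or `p_diff` (differing), weights 1 + Poisson(`weight_mean`−1)
  with `weight_mean = 2` by default. The ratio `p_same/p_diff` is the
  planted effect; at ratio 1 the graph is label-independent and observed
  homophily must match the permutation null.

One spec-level seed makes every generator deterministic; the corpus
generator derives all draws from it, so equal specs give byte-identical
corpora.

What the generator does *not* emulate: natural language (tokens are
synthetic strings, so tokenizer quality is untested by it), Japanese
morphology, bursty retweet cascades, topical correlation between moral
content and retweet structure beyond the planted label preference, and
bot-like repetition. Passing tests therefore certify the measurement
pipeline — parsing, scoring, aggregation, the homophily statistic and
its null — not the adequacy of any particular dictionary for real text.

## Numerical and degenerate-input choices

* Tie detection (tweet labels, user labels) on integer counts; no
  epsilon comparisons.
* Zero moral matches → undefined loading → filtered, with the discarded
  count reported via `message()`.
* Variance floor $10^{-12}$ separates "component of the data" from
  numerical residue in PCA; variance-explained fractions are renormalized
  over all components and sum to 1.
* All-identical pooled samples short-circuit the Kruskal–Wallis test to
  statistic 0, p-value 1 (the tie correction would otherwise divide by
  zero).
* Empty networks error in `network_homophily()` rather than returning an
  empty table, since a silent empty result usually signals an upstream
  filtering accident.
* The permutation null restores the caller's RNG state, so calling it
  does not perturb surrounding simulations.

## Problem sizes used by the test suite

The suite checks oracle equivalence on 200 random instances per
operation (token lists up to 20 tokens, graphs up to 30 nodes), mixture
recovery with 5 users × 1000 single-token tweets against a
3-standard-error band, and planted-homophily recovery on 500-node
networks across attachment ratios 0.5–4 with 10 seeds and a 100-draw
permutation null. These sizes put Monte-Carlo error well below the
effects being tested while keeping the default test run fast.

## Known limitations

* The fallback Japanese segmenter splits on character-class boundaries
  only; it exists so the pipeline runs untooled, and any real Japanese
  analysis should plug a morphological analyzer into `segmenter`.
* Dictionary matching is single-token; multi-word dictionary terms are
  rejected at parse time rather than silently mismatched.
* No negation or context handling: "not fair" scores as Fairness.
* The homophily statistic conditions on the observed graph; it does not
  model degree heterogeneity beyond what the permutation null captures.
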