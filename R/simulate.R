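# --- count-distribution specs -----------------------------------------------

#' Count-distribution specifications for the corpus generator
#'
#' `dist_constant(k)` always returns `k`; `dist_geometric(mean)` is a
#' shifted geometric on \{1, 2, ...\} with the given mean, matching the
#' heavily skewed tweets-per-user counts seen on social platforms (most
#' users post a handful of times, a few post a lot); `dist_poisson(mean)`
#' is a shifted Poisson on \{1, 2, ...\}.
#'
#' @param k,mean Distribution parameters; means must be >= 1.
#' @return A spec usable in [corpus_spec()].
#' @export
dist_constant <- function(k) {
  stopifnot(k >= 1)
  list(dist = "constant", k = k)
}

#' @rdname dist_constant
#' @export
dist_geometric <- function(mean) {
  stopifnot(mean >= 1)
  list(dist = "geometric", mean = mean)
}

#' @rdname dist_constant
#' @export
dist_poisson <- function(mean) {
  stopifnot(mean >= 1)
  list(dist = "poisson", mean = mean)
}

rcount <- function(n, spec) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- dist_constant(spec)
  switch(spec$dist,
    constant = rep(as.integer(spec$k), n),
    geometric = 1L + stats::rgeom(n, prob = 1 / spec$mean),
    poisson = 1L + stats::rpois(n, lambda = spec$mean - 1),
    stop("unknown count distribution: ", spec$dist)
  )
}

# --- specs -------------------------------------------------------------------

#' Specify a synthetic tweet corpus
#'
#' Parameters of the corpus generator. Defaults emulate the statistical
#' shape of a keyword-collected moral-discussion corpus: many users with a
#' skewed (geometric) tweet-count distribution, short token lists, a
#' minority of tokens drawn from the moral lexicon, and retweet events
#' that can prefer same-minded users.
#'
#' @param n_users Number of users.
#' @param tweets_per_user Count spec (number or [dist_constant()]-style
#'   list); default geometric with mean 3.
#' @param tokens_per_tweet Count spec; default geometric with mean 8.
#' @param foundation_mixture `NULL` (each user gets an independent uniform
#'   Dirichlet draw over the five foundations), a single 5-simplex vector
#'   shared by all users, or an `n_users` x 5 matrix of per-user weights.
#' @param moral_token_rate Probability that a token is drawn from the
#'   moral lexicon rather than the background vocabulary; default 0.2.
#' @param n_background Background vocabulary size (disjoint from the moral
#'   vocabulary by construction); default 200.
#' @param retweet_rate Probability that a tweet is also a retweet of
#'   another user's post; default 0.3.
#' @param p_same,p_diff Relative preference for retweeting users whose
#'   dominant mixture foundation matches (`p_same`) or differs
#'   (`p_diff`); defaults 1 and 1 (no planted homophily).
#' @param seed Integer seed; the generator is deterministic given the
#'   spec.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_users,
                        tweets_per_user = dist_geometric(3),
                        tokens_per_tweet = dist_geometric(8),
                        foundation_mixture = NULL,
                        moral_token_rate = 0.2,
                        n_background = 200,
                        retweet_rate = 0.3,
                        p_same = 1, p_diff = 1,
                        seed = 1) {
  stopifnot(n_users >= 1, moral_token_rate >= 0, moral_token_rate <= 1,
            retweet_rate >= 0, retweet_rate <= 1,
            p_same >= 0, p_diff >= 0, n_background >= 1)
  if (!is.null(foundation_mixture)) {
    m <- foundation_mixture
    if (is.numeric(m) && is.null(dim(m))) m <- matrix(m, nrow = 1)
    stopifnot(ncol(m) == 5, all(m >= 0),
              all(abs(rowSums(m) - 1) < 1e-8))
    foundation_mixture <- m
  }
  structure(
    list(n_users = as.integer(n_users), tweets_per_user = tweets_per_user,
         tokens_per_tweet = tokens_per_tweet,
         foundation_mixture = foundation_mixture,
         moral_token_rate = moral_token_rate,
         n_background = as.integer(n_background),
         retweet_rate = retweet_rate, p_same = p_same, p_diff = p_diff,
         seed = seed),
    class = "corpus_spec"
  )
}

#' Specify a synthetic planted-homophily network
#'
#' Each node draws a foundation label from `label_distribution`; each
#' unordered node pair is joined with probability `p_same` when the labels
#' match and `p_diff` otherwise, with an integer weight of mean
#' `weight_mean`. The ratio `p_same / p_diff` is the planted homophily
#' strength.
#'
#' @param n_nodes Number of nodes.
#' @param label_distribution 5-simplex weights over
#'   [moral_foundations()]; default uniform.
#' @param p_same,p_diff Edge probabilities in \[0, 1\].
#' @param weight_mean Mean edge weight (>= 1); weights are
#'   1 + Poisson(weight_mean - 1). Default 2.
#' @param seed Integer seed.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(n_nodes, label_distribution = rep(0.2, 5),
                         p_same = 0.05, p_diff = 0.05,
                         weight_mean = 2, seed = 1) {
  stopifnot(n_nodes >= 1, length(label_distribution) == 5,
            all(label_distribution >= 0), sum(label_distribution) > 0,
            p_same >= 0, p_same <= 1, p_diff >= 0, p_diff <= 1,
            weight_mean >= 1)
  structure(
    list(n_nodes = as.integer(n_nodes),
         label_distribution = label_distribution / sum(label_distribution),
         p_same = p_same, p_diff = p_diff, weight_mean = weight_mean,
         seed = seed),
    class = "network_spec"
  )
}

# --- generators --------------------------------------------------------------

#' Generate a synthetic moral lexicon
#'
#' Builds a foundation-disjoint lexicon with the standard category layout:
#' a virtue and a vice category for each of the five foundations plus one
#' general-morality category, each with `words_per_category` synthetic
#' entries. Category vocabularies use distinct fixed prefixes so no stem
#' of one foundation can match a word of another, keeping expected
#' loadings analytic.
#'
#' @param words_per_category Entries per category (>= 1).
#' @param stems_fraction Probability that an entry is a prefix stem.
#' @param seed Integer seed; the same seed yields an identical lexicon.
#' @return A `moral_lexicon` with 11 categories and
#'   `11 * words_per_category` entries.
#' @export
generate_lexicon <- function(words_per_category, stems_fraction = 0,
                             seed = 1) {
  stopifnot(words_per_category >= 1,
            stems_fraction >= 0, stems_fraction <= 1)
  cat_names <- c("HarmVirtue", "HarmVice", "FairnessVirtue", "FairnessVice",
                 "IngroupVirtue", "IngroupVice", "AuthorityVirtue",
                 "AuthorityVice", "PurityVirtue", "PurityVice",
                 "MoralityGeneral")
  prefixes <- c("carev", "carex", "fairv", "fairx", "ingrv", "ingrx",
                "authv", "authx", "purev", "purex", "genrl")
  categories <- tibble::tibble(
    id = seq_along(cat_names), name = cat_names,
    foundation = vapply(cat_names, foundation_from_category_name, "",
                        USE.NAMES = FALSE),
    polarity = vapply(cat_names, polarity_from_category_name, "",
                      USE.NAMES = FALSE)
  )
  with_seed(seed, {
    pats <- character(0); stems <- logical(0); catsets <- list()
    for (ci in seq_along(cat_names)) {
      words <- character(0)
      while (length(words) < words_per_category) {
        w <- paste0(prefixes[ci],
                    paste(sample(letters, 5, replace = TRUE), collapse = ""))
        if (!w %in% words) words <- c(words, w)
      }
      is_stem <- stats::runif(words_per_category) < stems_fraction
      pats <- c(pats, words); stems <- c(stems, is_stem)
      catsets <- c(catsets, rep(list(ci), words_per_category))
    }
    moral_lexicon(
      name = sprintf("synthetic-%d", seed),
      categories = categories,
      entries = tibble::tibble(pattern = pats, is_stem = stems,
                               categories = catsets)
    )
  })
}

#' Generate a synthetic tweet corpus with known ground truth
#'
#' Draws users, per-user tweet counts, token lists and retweet events
#' according to a [corpus_spec()]. Each moral token's foundation is drawn
#' i.i.d. from the user's foundation mixture, and a uniform word is then
#' drawn from that foundation's vocabulary (virtue and vice pooled);
#' background tokens come from a disjoint `bg` vocabulary. Retweet
#' targets are drawn with weight `p_same` for users sharing the
#' retweeter's dominant mixture foundation and `p_diff` otherwise.
#'
#' @param spec A [corpus_spec()].
#' @param lexicon A foundation-disjoint `moral_lexicon` (e.g. from
#'   [generate_lexicon()]); every foundation must have at least one entry.
#' @return A list with `tweets` (tibble: `tweet_id`, `user_id`, `tokens`
#'   list column, `lang`, `retweet_of_user`), `mixtures` (ground-truth
#'   `n_users` x 5 matrix, row names = user ids), and `dominant`
#'   (named character vector of each user's dominant mixture foundation).
#' @export
generate_corpus <- function(spec, lexicon) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(lexicon, "moral_lexicon"))
  fnd <- moral_foundations()
  cat_found <- stats::setNames(lexicon$categories$foundation,
                               lexicon$categories$id)
  vocab <- lapply(fnd, function(f) {
    hit <- vapply(lexicon$entries$categories,
                  function(s) any(cat_found[as.character(s)] == f), NA)
    lexicon$entries$pattern[hit]
  })
  names(vocab) <- fnd
  if (any(lengths(vocab) == 0)) {
    stop("lexicon must have at least one entry per foundation")
  }
  bg_vocab <- sprintf("bg%04d", seq_len(spec$n_background))
  user_ids <- sprintf("u%05d", seq_len(spec$n_users))

  with_seed(spec$seed, {
    mix <- spec$foundation_mixture
    if (is.null(mix)) {
      mix <- matrix(stats::rgamma(spec$n_users * 5, shape = 1),
                    nrow = spec$n_users)
      mix <- mix / rowSums(mix)
    } else if (nrow(mix) == 1 && spec$n_users > 1) {
      mix <- matrix(rep(as.numeric(mix), each = spec$n_users),
                    nrow = spec$n_users)
    }
    stopifnot(nrow(mix) == spec$n_users)
    dimnames(mix) <- list(user_ids, fnd)
    dominant <- fnd[apply(mix, 1, which.max)]
    names(dominant) <- user_ids

    n_tweets <- rcount(spec$n_users, spec$tweets_per_user)
    tw_user <- rep(user_ids, n_tweets)
    tw_user_idx <- rep(seq_len(spec$n_users), n_tweets)
    total <- length(tw_user)
    n_tok <- rcount(total, spec$tokens_per_tweet)

    tokens <- vector("list", total)
    for (t in seq_len(total)) {
      k <- n_tok[t]
      moral <- stats::runif(k) < spec$moral_token_rate
      toks <- character(k)
      if (any(moral)) {
        f_idx <- sample.int(5, sum(moral), replace = TRUE,
                            prob = mix[tw_user_idx[t], ])
        toks[moral] <- vapply(f_idx, function(fi) {
          v <- vocab[[fi]]
          v[sample.int(length(v), 1L)]
        }, "")
      }
      if (any(!moral)) {
        toks[!moral] <- bg_vocab[sample.int(spec$n_background, sum(!moral),
                                            replace = TRUE)]
      }
      tokens[[t]] <- toks
    }

    retweet_of <- rep(NA_character_, total)
    if (spec$retweet_rate > 0 && spec$n_users > 1) {
      is_rt <- stats::runif(total) < spec$retweet_rate
      for (t in which(is_rt)) {
        u <- tw_user_idx[t]
        w <- ifelse(dominant == dominant[u], spec$p_same, spec$p_diff)
        w[u] <- 0
        if (sum(w) > 0) {
          retweet_of[t] <- user_ids[sample.int(spec$n_users, 1L, prob = w)]
        }
      }
    }

    list(
      tweets = tibble::tibble(
        tweet_id = sprintf("t%07d", seq_len(total)),
        user_id = tw_user,
        tokens = tokens,
        lang = "en",
        retweet_of_user = retweet_of
      ),
      mixtures = mix,
      dominant = dominant
    )
  })
}

#' Generate a planted-homophily retweet network
#'
#' Draws node labels from the spec's label distribution and joins each
#' unordered pair independently: with probability `p_same` when the two
#' labels match and `p_diff` otherwise. Edge weights are
#' 1 + Poisson(`weight_mean` - 1). The returned network contains only the
#' endpoints of realized edges (matching the pipeline's construction);
#' the full ground-truth labeling is returned alongside.
#'
#' @param spec A [network_spec()].
#' @return A list with `network` (a `retweet_network`) and `labels`
#'   (tibble `user_id`, `label` for all `n_nodes` nodes).
#' @export
generate_retweet_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  fnd <- moral_foundations()
  n <- spec$n_nodes
  ids <- sprintf("n%05d", seq_len(n))
  with_seed(spec$seed, {
    labels <- sample(fnd, n, replace = TRUE, prob = spec$label_distribution)
    if (n >= 2) {
      i <- rep(seq_len(n - 1L), (n - 1L):1L)
      j <- sequence((n - 1L):1L) + i
      same <- labels[i] == labels[j]
      p <- ifelse(same, spec$p_same, spec$p_diff)
      keep <- stats::runif(length(i)) < p
      i <- i[keep]; j <- j[keep]
      weight <- 1L + stats::rpois(length(i), lambda = spec$weight_mean - 1)
    } else {
      i <- j <- integer(0); weight <- integer(0)
    }
    edges <- tibble::tibble(user_a = ids[i], user_b = ids[j],
                            weight = as.numeric(weight))
    ends <- unique(c(edges$user_a, edges$user_b))
    nodes <- tibble::tibble(user_id = ids, label = labels)
    network <- retweet_network(nodes[nodes$user_id %in% ends, , drop = FALSE],
                               edges)
    list(network = network, labels = nodes)
  })
}
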