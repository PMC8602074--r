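# Shared fixtures and independent brute-force oracles. The oracles scan
# every entry / edge linearly and never share code with the implementation
# paths they check.

toy_dic_lines <- function() {
  c("%",
    "01\tHarmVirtue", "02\tHarmVice",
    "03\tFairnessVirtue", "04\tFairnessVice",
    "05\tIngroupVirtue", "06\tIngroupVice",
    "07\tAuthorityVirtue", "08\tAuthorityVice",
    "09\tPurityVirtue", "10\tPurityVice",
    "11\tMoralityGeneral",
    "%",
    "kill\t02", "killer*\t02", "care\t01",
    "fair\t03", "cheat*\t04",
    "loyal\t05", "betray*\t06",
    "obey\t07", "rebel*\t08",
    "pure\t09", "filth*\t10",
    "moral*\t11")
}

toy_lexicon <- function() parse_liwc_dic(toy_dic_lines())

triangle_network <- function() {
  retweet_network(
    nodes = data.frame(user_id = c("u1", "u2", "u3"),
                       label = c("CARE", "CARE", "FAIRNESS")),
    edges = data.frame(user_a = c("u1", "u1", "u2"),
                       user_b = c("u2", "u3", "u3"),
                       weight = c(1, 1, 1))
  )
}

# linear scan over all entries
oracle_match_token <- function(lexicon, token) {
  hits <- integer(0)
  for (i in seq_len(nrow(lexicon$entries))) {
    p <- lexicon$entries$pattern[i]
    if (lexicon$entries$is_stem[i]) {
      ok <- nchar(token) >= nchar(p) && substr(token, 1, nchar(p)) == p
    } else {
      ok <- token == p
    }
    if (ok) hits <- c(hits, lexicon$entries$categories[[i]])
  }
  sort(unique(hits))
}

# loops foundation x token x entry
oracle_moral_loading <- function(tokens, lexicon) {
  fnd <- moral_foundations()
  cat_f <- setNames(lexicon$categories$foundation, lexicon$categories$id)
  counts <- setNames(integer(5), fnd)
  denom <- 0L
  for (tk in tokens) {
    fs <- unique(cat_f[as.character(oracle_match_token(lexicon, tk))])
    fs <- fs[fs != "GENERAL"]
    if (length(fs) > 0) denom <- denom + 1L
    for (f in fnd) if (f %in% fs) counts[f] <- counts[f] + 1L
  }
  list(counts = counts, n_moral_tokens = denom,
       ml = if (denom > 0) counts / denom else setNames(rep(NA_real_, 5), fnd))
}

# enumerate every incident edge of node i
oracle_node_homophily <- function(network, i) {
  e <- network$edges
  lab <- setNames(network$nodes$label, network$nodes$user_id)
  num <- 0; den <- 0
  for (r in seq_len(nrow(e))) {
    if (e$user_a[r] == i || e$user_b[r] == i) {
      other <- if (e$user_a[r] == i) e$user_b[r] else e$user_a[r]
      den <- den + e$weight[r]
      if (lab[[other]] == lab[[i]]) num <- num + e$weight[r]
    }
  }
  num / den
}

# small random lexicon over a tiny alphabet so prefixes collide often;
# entries may carry several categories (multi-foundation tokens)
random_lexicon <- function(n_entries = 12, alphabet = c("a", "b", "c")) {
  cats <- data.frame(
    id = 1:11,
    name = c("HarmVirtue", "HarmVice", "FairnessVirtue", "FairnessVice",
             "IngroupVirtue", "IngroupVice", "AuthorityVirtue",
             "AuthorityVice", "PurityVirtue", "PurityVice",
             "MoralityGeneral"),
    stringsAsFactors = FALSE
  )
  cats$foundation <- vapply(cats$name, moralnet:::foundation_from_category_name, "")
  cats$polarity <- vapply(cats$name, moralnet:::polarity_from_category_name, "")
  seen <- character(0)
  pats <- character(0); stems <- logical(0); sets <- list()
  while (length(pats) < n_entries) {
    p <- paste(sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = "")
    s <- runif(1) < 0.5
    key <- paste0(p, s)
    if (key %in% seen) next
    seen <- c(seen, key)
    pats <- c(pats, p); stems <- c(stems, s)
    sets <- c(sets, list(sample(1:11, sample(1:2, 1))))
  }
  moral_lexicon("random", cats,
                tibble::tibble(pattern = pats, is_stem = stems,
                               categories = sets))
}

random_tokens <- function(n_max = 20, alphabet = c("a", "b", "c")) {
  n <- sample(1:n_max, 1)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(1:5, 1), replace = TRUE), collapse = "")
  }, "")
}

# random connected-enough weighted graph on <= n_max nodes, with every
# node an edge endpoint
random_network <- function(n_max = 30) {
  n <- sample(3:n_max, 1)
  ids <- sprintf("r%02d", seq_len(n))
  labels <- sample(moral_foundations(), n, replace = TRUE)
  # a random spanning path guarantees no isolated node
  ord <- sample(ids)
  a <- ord[-n]; b <- ord[-1]
  extra <- max(1L, rpois(1, n))
  for (k in seq_len(extra)) {
    pr <- sample(ids, 2)
    a <- c(a, pr[1]); b <- c(b, pr[2])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  edges <- data.frame(user_a = lo[keep], user_b = hi[keep],
                      weight = sample(1:5, sum(keep), replace = TRUE))
  retweet_network(data.frame(user_id = ids, label = labels), edges)
}

# fixture corpus for exclusion-rule checks: labels chosen per tweet
labels_fixture <- function() {
  tibble::tibble(
    tweet_id = sprintf("t%02d", 1:15),
    user_id = c(rep("uA", 3), rep("uB", 2), "uC", rep("uD", 5),
                rep("uE", 4)),
    retweet_of_user = NA_character_,
    labels = c("CARE", "CARE", "FAIRNESS",         # uA -> CARE
               "CARE", "FAIRNESS",                 # uB -> tie, EXCLUDED
               "PURITY",                           # uC -> single tweet, EXCLUDED
               rep("PURITY", 5),                   # uD -> PURITY
               "CARE", "CARE", "INGROUP", "INGROUP") # uE -> tie, EXCLUDED
  )
}
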