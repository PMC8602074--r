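test_that("tokenize strips URLs, mentions and hashtag symbols and lowercases", {
  expect_equal(tokenize("Killing is #immoral http://t.co/x", "en"),
               c("killing", "immoral"))
  expect_equal(tokenize("", "en"), character(0))
  expect_equal(tokenize("@bob MORAL", "en"), "moral")
  expect_equal(tokenize("check www.example.com out!", "en"),
               c("check", "out"))
})

test_that("tokenize honours a custom stop list and a custom segmenter", {
  expect_equal(tokenize("the moral law", "en", stopwords = character(0)),
               c("the", "moral", "law"))
  seg <- function(x) strsplit(trimws(x), "/", fixed = TRUE)[[1]]
  expect_equal(tokenize("A/B/C", "ja", segmenter = seg), c("a", "b", "c"))
  expect_error(tokenize("x", "fr"))
})

test_that("the naive Japanese fallback splits at character-class boundaries", {
  toks <- tokenize("道徳は大切", "ja")
  expect_equal(toks, c("道徳", "は", "大切"))
})

test_that("moral_loading normalizes per-foundation counts by total moral tokens", {
  lex <- toy_lexicon()
  ld <- moral_loading(c("kill", "fair", "loyal", "fair"), lex)
  expect_equal(unname(ld$ml), c(0.25, 0.5, 0.25, 0, 0))
  expect_equal(ld$n_moral_tokens, 4L)

  single <- moral_loading(c("care", "banana"), lex)
  expect_equal(unname(single$ml), c(1, 0, 0, 0, 0))

  none <- moral_loading(c("banana", "apple"), lex)
  expect_equal(none$n_moral_tokens, 0L)
  expect_true(all(is.na(none$ml)))
})

test_that("GENERAL matches are excluded from numerator and denominator", {
  lex <- toy_lexicon()
  only_general <- moral_loading(c("moral", "morality"), lex)
  expect_equal(only_general$n_moral_tokens, 0L)

  mixed <- moral_loading(c("moral", "kill"), lex)
  expect_equal(mixed$n_moral_tokens, 1L)
  expect_equal(unname(mixed$ml), c(1, 0, 0, 0, 0))
})

test_that("type counting collapses repeated tokens, occurrence counting does not", {
  lex <- toy_lexicon()
  occ <- moral_loading(c("fair", "fair", "kill"), lex)
  expect_equal(unname(occ$ml), c(1 / 3, 2 / 3, 0, 0, 0))
  typ <- moral_loading(c("fair", "fair", "kill"), lex, count = "types")
  expect_equal(unname(typ$ml), c(0.5, 0.5, 0, 0, 0))
})

test_that("label_tweet returns the full argmax set and rejects undefined loadings", {
  lex <- toy_lexicon()
  expect_equal(label_tweet(moral_loading(c("kill", "fair", "loyal", "fair"), lex)),
               "FAIRNESS")
  expect_equal(label_tweet(moral_loading(c("kill", "fair"), lex)),
               c("CARE", "FAIRNESS"))
  expect_equal(label_tweet(moral_loading("care", lex)), "CARE")
  expect_error(label_tweet(moral_loading("banana", lex)), "undefined")
})

test_that("moral_loading is invariant under token permutation", {
  set.seed(11)
  lex <- toy_lexicon()
  for (rep in 1:20) {
    toks <- sample(c("kill", "fair", "loyal", "obey", "pure", "banana",
                     "moral", "cheater"), sample(2:8, 1), replace = TRUE)
    a <- moral_loading(toks, lex)
    b <- moral_loading(sample(toks), lex)
    expect_equal(a$ml, b$ml)
    expect_equal(a$n_moral_tokens, b$n_moral_tokens)
  }
})

test_that("moral_loading matches the brute-force oracle on random instances", {
  set.seed(23)
  for (rep in 1:60) {
    lex <- random_lexicon()
    toks <- random_tokens()
    got <- moral_loading(toks, lex)
    want <- oracle_moral_loading(toks, lex)
    expect_equal(got$counts, want$counts)
    expect_equal(got$n_moral_tokens, want$n_moral_tokens)
    expect_equal(got$ml, want$ml)
  }
})

test_that("loading vectors sum to 1 on disjoint lexicons and to [1,5] otherwise", {
  set.seed(5)
  disjoint <- generate_lexicon(5, stems_fraction = 0.4, seed = 2)
  vocab <- disjoint$entries$pattern
  for (rep in 1:20) {
    toks <- sample(vocab, sample(1:10, 1), replace = TRUE)
    ld <- moral_loading(toks, disjoint)
    expect_equal(sum(ld$ml), 1)
  }
  for (rep in 1:30) {
    lex <- random_lexicon()
    toks <- random_tokens()
    ld <- moral_loading(toks, lex)
    if (ld$n_moral_tokens > 0) {
      expect_gte(sum(ld$ml), 1)
      expect_lte(sum(ld$ml), 5)
    }
  }
})

test_that("filter_moral_corpus keeps only defined loadings, in input order", {
  lex <- toy_lexicon()
  corpus <- tibble::tibble(
    tweet_id = c("t1", "t2", "t3"),
    user_id = c("u1", "u1", "u2"),
    tokens = list(c("kill", "fair"), c("banana"), c("loyal"))
  )
  expect_message(out <- filter_moral_corpus(corpus, lex), "1 of 3")
  expect_equal(out$tweet_id, c("t1", "t3"))
  expect_equal(out$labels, c("CARE|FAIRNESS", "INGROUP"))
  expect_true(all(out$n_moral_tokens > 0))

  empty <- suppressMessages(
    filter_moral_corpus(corpus[0, ], lex)
  )
  expect_equal(nrow(empty), 0)

  general_only <- tibble::tibble(tweet_id = "t1", user_id = "u1",
                                 tokens = list(c("moral", "morality")))
  expect_equal(nrow(suppressMessages(filter_moral_corpus(general_only, lex))), 0)
})

test_that("filter_moral_corpus tokenizes raw text and drops self-retweets", {
  lex <- toy_lexicon()
  corpus <- tibble::tibble(
    tweet_id = c("t1", "t2"),
    user_id = c("u1", "u2"),
    text = c("Killing is #immoral", "so loyal @u9"),
    lang = "en",
    retweet_of_user = c("u1", "u7")
  )
  out <- suppressMessages(filter_moral_corpus(corpus, lex))
  # "killing" matches nothing in the toy lexicon ("kill" exact, "killer*");
  # t2's "loyal" does
  expect_equal(out$tweet_id, "t2")
  expect_equal(out$retweet_of_user, "u7")

  # self-retweet on t1 was nulled at ingest even though t1 is filtered
  corpus2 <- tibble::tibble(tweet_id = "t1", user_id = "u1",
                            tokens = list("kill"), retweet_of_user = "u1")
  out2 <- suppressMessages(filter_moral_corpus(corpus2, lex))
  expect_true(is.na(out2$retweet_of_user))
})
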