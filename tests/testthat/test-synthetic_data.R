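test_that("generated lexicons have the standard category layout", {
  lex <- generate_lexicon(2, stems_fraction = 0, seed = 1)
  expect_equal(nrow(lex$entries), 22)
  expect_false(any(lex$entries$is_stem))
  general_ids <- lex$categories$id[lex$categories$foundation == "GENERAL"]
  n_general <- sum(vapply(lex$entries$categories,
                          function(s) any(s %in% general_ids), NA))
  expect_equal(n_general, 2)

  all_stems <- generate_lexicon(3, stems_fraction = 1, seed = 2)
  expect_true(all(all_stems$entries$is_stem))

  expect_identical(generate_lexicon(4, 0.5, seed = 9),
                   generate_lexicon(4, 0.5, seed = 9))
  expect_false(identical(generate_lexicon(4, 0.5, seed = 9)$entries,
                         generate_lexicon(4, 0.5, seed = 10)$entries))
})

test_that("generated lexicons are foundation-disjoint", {
  lex <- generate_lexicon(5, stems_fraction = 0.5, seed = 3)
  cat_f <- setNames(lex$categories$foundation, lex$categories$id)
  vocab_f <- lapply(lex$entries$categories,
                    function(s) unique(cat_f[as.character(s)]))
  expect_true(all(lengths(vocab_f) == 1))
  # with stems, no pattern of one foundation prefixes a word of another
  for (i in seq_len(nrow(lex$entries))) {
    if (!lex$entries$is_stem[i]) next
    hits <- startsWith(lex$entries$pattern, lex$entries$pattern[i])
    expect_true(all(unlist(vocab_f[hits]) == vocab_f[[i]]))
  }
})

test_that("corpus generation respects the moral token rate", {
  lex <- generate_lexicon(3, seed = 4)
  none <- generate_corpus(corpus_spec(10, moral_token_rate = 0, seed = 5), lex)
  expect_equal(nrow(suppressMessages(filter_moral_corpus(none$tweets, lex))), 0)

  all_moral <- generate_corpus(
    corpus_spec(10, moral_token_rate = 1, seed = 6), lex)
  labeled <- suppressMessages(filter_moral_corpus(all_moral$tweets, lex))
  expect_equal(nrow(labeled), nrow(all_moral$tweets))
})

test_that("a degenerate mixture yields a single label everywhere", {
  lex <- generate_lexicon(3, seed = 7)
  corpus <- generate_corpus(
    corpus_spec(10, foundation_mixture = c(1, 0, 0, 0, 0),
                moral_token_rate = 1, seed = 8), lex)
  labeled <- suppressMessages(filter_moral_corpus(corpus$tweets, lex))
  expect_true(all(labeled$labels == "CARE"))
  expect_equal(unname(corpus$dominant), rep("CARE", 10))
})

test_that("corpus generation is deterministic under the spec seed", {
  lex <- generate_lexicon(3, seed = 9)
  spec <- corpus_spec(15, retweet_rate = 0.5, seed = 10)
  a <- generate_corpus(spec, lex)
  b <- generate_corpus(spec, lex)
  expect_identical(a, b)
  c2 <- generate_corpus(corpus_spec(15, retweet_rate = 0.5, seed = 11), lex)
  expect_false(identical(a$tweets, c2$tweets))
})

test_that("planted attachment probabilities drive homophily to its extremes", {
  all_same <- generate_retweet_network(
    network_spec(40, p_same = 1, p_diff = 0, seed = 12))
  hom <- network_homophily(all_same$network)
  expect_true(all(hom$per_foundation$H == 1))

  all_diff <- generate_retweet_network(
    network_spec(40, p_same = 0, p_diff = 1, seed = 13))
  hom2 <- network_homophily(all_diff$network)
  expect_true(all(hom2$per_node$h == 0))
})

test_that("network generation is deterministic and honours the label distribution", {
  spec <- network_spec(60, p_same = 0.2, p_diff = 0.1, seed = 14)
  a <- generate_retweet_network(spec)
  b <- generate_retweet_network(spec)
  expect_identical(a, b)

  skew <- generate_retweet_network(
    network_spec(300, label_distribution = c(1, 0, 0, 0, 0),
                 p_same = 0.05, seed = 15))
  expect_true(all(skew$labels$label == "CARE"))
  expect_true(all(skew$network$edges$weight >= 1))
})

test_that("retweet events in the corpus generator link existing users", {
  lex <- generate_lexicon(3, seed = 16)
  corpus <- generate_corpus(
    corpus_spec(20, retweet_rate = 1, p_same = 4, p_diff = 1, seed = 17), lex)
  rt <- corpus$tweets$retweet_of_user
  expect_true(any(!is.na(rt)))
  expect_true(all(rt[!is.na(rt)] %in% corpus$tweets$user_id))
  expect_true(all(rt[!is.na(rt)] != corpus$tweets$user_id[!is.na(rt)]))
})

test_that("count-distribution specs produce values in their support", {
  set.seed(18)
  expect_true(all(moralnet:::rcount(50, dist_constant(3)) == 3))
  g <- moralnet:::rcount(2000, dist_geometric(3))
  expect_true(all(g >= 1))
  expect_equal(mean(g), 3, tolerance = 0.2)
  p <- moralnet:::rcount(2000, dist_poisson(4))
  expect_true(all(p >= 1))
  expect_equal(mean(p), 4, tolerance = 0.2)
})
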