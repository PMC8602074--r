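profiles_tbl <- function(ids, labels) {
  tibble::tibble(user_id = ids, label = labels)
}

rt_tweets <- function(from, to) {
  tibble::tibble(
    tweet_id = sprintf("t%03d", seq_along(from)),
    user_id = from, retweet_of_user = to
  )
}

test_that("retweet events accumulate onto undirected weighted edges", {
  prof <- profiles_tbl(c("u1", "u2"), c("CARE", "PURITY"))
  net <- build_retweet_network(rt_tweets(rep("u1", 3), rep("u2", 3)), prof)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_setequal(net$nodes$user_id, c("u1", "u2"))

  # reciprocal retweets land on the same weight
  both <- build_retweet_network(rt_tweets(c("u1", "u2"), c("u2", "u1")), prof)
  expect_equal(both$edges$weight, 2)

  # unweighted mode flattens weights to 1
  flat <- build_retweet_network(rt_tweets(rep("u1", 3), rep("u2", 3)), prof,
                                weighted = FALSE)
  expect_equal(flat$edges$weight, 1)
})

test_that("edges to excluded or unprofiled users are dropped", {
  prof <- profiles_tbl(c("u1", "u2", "u3"), c("CARE", "EXCLUDED", "PURITY"))
  net <- build_retweet_network(rt_tweets(c("u1", "u1"), c("u2", "u3")), prof)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes$user_id, c("u1", "u3"))

  none <- build_retweet_network(rt_tweets("u1", NA_character_), prof)
  expect_equal(nrow(none$nodes), 0)
  expect_equal(nrow(none$edges), 0)
})

test_that("the network constructor enforces its invariants", {
  expect_error(retweet_network(
    data.frame(user_id = "u1", label = "CARE"),
    data.frame(user_a = "u1", user_b = "u1", weight = 1)), "self-loop")
  expect_error(retweet_network(
    data.frame(user_id = c("u1", "u2"), label = c("CARE", "EXCLUDED")),
    data.frame(user_a = "u1", user_b = "u2", weight = 1)), "label")
  expect_error(retweet_network(
    data.frame(user_id = c("u1", "u2"), label = c("CARE", "CARE")),
    data.frame(user_a = "u1", user_b = "u2", weight = 0)), "weight")
})

test_that("triangle homophily matches hand evaluation", {
  net <- triangle_network()
  expect_equal(node_homophily(net, "u1"), 0.5)
  expect_equal(node_homophily(net, "u3"), 0)
  hom <- network_homophily(net)
  pf <- hom$per_foundation
  expect_equal(pf$H[pf$foundation == "CARE"], 0.5)
  expect_equal(pf$H[pf$foundation == "FAIRNESS"], 0)
  expect_equal(pf$n_nodes, c(2L, 1L))
  # foundations with no nodes are absent, not zero
  expect_false("PURITY" %in% pf$foundation)
})

test_that("weights enter node homophily, and a same-label star is fully homophilous", {
  net <- retweet_network(
    data.frame(user_id = c("u1", "u2", "u3"),
               label = c("CARE", "FAIRNESS", "CARE")),
    data.frame(user_a = c("u1", "u1"), user_b = c("u2", "u3"),
               weight = c(5, 5)))
  expect_equal(node_homophily(net, "u1"), 0.5)

  star <- retweet_network(
    data.frame(user_id = c("c", "l1", "l2", "l3"), label = rep("CARE", 4)),
    data.frame(user_a = rep("c", 3), user_b = c("l1", "l2", "l3"),
               weight = 1))
  expect_equal(node_homophily(star, "c"), 1)
  expect_equal(network_homophily(star)$per_foundation$H, 1)
})

test_that("homophily is invariant under scaling all edge weights", {
  set.seed(17)
  for (rep in 1:5) {
    net <- random_network()
    doubled <- retweet_network(net$nodes,
                               transform(net$edges, weight = weight * 2))
    a <- network_homophily(net)
    b <- network_homophily(doubled)
    expect_equal(a$per_node$h, b$per_node$h)
    expect_equal(a$per_foundation$H, b$per_foundation$H)
  }
})

test_that("node homophily matches the brute-force oracle on random graphs", {
  set.seed(19)
  for (rep in 1:30) {
    net <- random_network()
    for (u in sample(net$nodes$user_id, min(5, nrow(net$nodes)))) {
      expect_equal(node_homophily(net, u), oracle_node_homophily(net, u))
    }
  }
})

test_that("per-foundation H is the unweighted mean of member node scores", {
  set.seed(29)
  net <- random_network()
  hom <- network_homophily(net)
  for (i in seq_len(nrow(hom$per_foundation))) {
    f <- hom$per_foundation$foundation[i]
    members <- hom$per_node$h[hom$per_node$label == f]
    expect_equal(hom$per_foundation$H[i], mean(members))
    expect_gte(hom$per_foundation$H[i], 0)
    expect_lte(hom$per_foundation$H[i], 1)
  }
})

test_that("homophily of an empty network and of missing nodes errors", {
  empty <- retweet_network(
    tibble::tibble(user_id = character(), label = character()),
    tibble::tibble(user_a = character(), user_b = character(),
                   weight = numeric()))
  expect_error(network_homophily(empty), "empty")
  expect_error(node_homophily(triangle_network(), "nope"), "not in the network")
  iso <- retweet_network(
    tibble::tibble(user_id = c("u1", "u2", "u3"),
                   label = c("CARE", "CARE", "CARE")),
    tibble::tibble(user_a = "u1", user_b = "u2", weight = 1))
  expect_error(node_homophily(iso, "u3"), "no incident edges")
})

test_that("k-core pruning matches hand evaluation and is idempotent", {
  tri <- triangle_network()
  expect_equal(k_core(tri, 2), tri)
  expect_equal(k_core(tri, 0), tri)

  path3 <- retweet_network(
    data.frame(user_id = c("a", "b", "c"), label = rep("CARE", 3)),
    data.frame(user_a = c("a", "b"), user_b = c("b", "c"), weight = 1))
  expect_equal(nrow(k_core(path3, 2)$nodes), 0)
  expect_equal(nrow(k_core(path3, 1)$nodes), 3)

  set.seed(37)
  for (rep in 1:5) {
    net <- random_network()
    for (k in 0:3) {
      once <- k_core(net, k)
      expect_equal(k_core(once, k), once)
    }
  }
})

test_that("permutation null is reproducible and exact on forced cases", {
  net <- triangle_network()
  # every placement of labels {A, A, B} on a triangle is isomorphic,
  # so each null draw gives H_A = 1/2 and H_B = 0 exactly
  null <- permutation_null(net, n_perm = 50, seed = 1)
  expect_true(all(null$samples[, "CARE"] == 0.5))
  expect_true(all(null$samples[, "FAIRNESS"] == 0))
  expect_true(all(is.na(null$samples[, "PURITY"])))
  expect_equal(null$summary$null_mean,
               c(0.5, 0))

  # all-same-label network: shuffling is the identity on labels
  star <- retweet_network(
    data.frame(user_id = c("c", "l1", "l2"), label = rep("CARE", 3)),
    data.frame(user_a = rep("c", 2), user_b = c("l1", "l2"), weight = 1))
  snull <- permutation_null(star, n_perm = 10, seed = 2)
  expect_true(all(snull$samples[, "CARE"] == 1))

  # determinism under a fixed seed
  set.seed(41); net2 <- random_network()
  x <- permutation_null(net2, n_perm = 20, seed = 7)
  y <- permutation_null(net2, n_perm = 20, seed = 7)
  expect_identical(x$samples, y$samples)
})

test_that("graph exports round through igraph, TSV and GEXF", {
  net <- triangle_network()
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$label, c("CARE", "CARE", "FAIRNESS"))

  tsv <- tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 3)
  expect_equal(sort(names(back)), c("user_a", "user_b", "weight"))

  gexf <- tempfile(fileext = ".gexf")
  write_gexf(net, gexf)
  doc <- readLines(gexf)
  expect_true(any(grepl("gexf.net", doc)))
  expect_equal(sum(grepl("<node ", doc)), 3)
  expect_equal(sum(grepl("<edge ", doc)), 3)
})
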