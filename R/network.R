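#' Construct a retweet network object
#'
#' A weighted undirected user graph. Nodes carry a single moral-foundation
#' label; edge weights are positive retweet counts between the pair.
#' Self-loops and `EXCLUDED` endpoints are rejected.
#'
#' @param nodes Data frame with columns `user_id` and `label` (a
#'   foundation from [moral_foundations()]).
#' @param edges Data frame with columns `user_a`, `user_b`, `weight`.
#'   Pairs are stored in canonical (sorted) order.
#' @return An object of class `retweet_network`.
#' @export
retweet_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("user_id", "label") %in% names(nodes)),
            all(c("user_a", "user_b", "weight") %in% names(edges)))
  nodes$user_id <- as.character(nodes$user_id)
  if (anyDuplicated(nodes$user_id)) stop("duplicate node user_ids")
  if (!all(nodes$label %in% moral_foundations())) {
    stop("every node must carry one of the five foundation labels")
  }
  if (nrow(edges) > 0) {
    edges$user_a <- as.character(edges$user_a)
    edges$user_b <- as.character(edges$user_b)
    if (any(edges$user_a == edges$user_b)) stop("self-loops are not allowed")
    if (any(edges$weight < 1)) stop("edge weights must be >= 1")
    swap <- edges$user_a > edges$user_b
    tmp <- edges$user_a[swap]
    edges$user_a[swap] <- edges$user_b[swap]
    edges$user_b[swap] <- tmp
    key <- paste(edges$user_a, edges$user_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges for the same pair")
    ends <- unique(c(edges$user_a, edges$user_b))
    if (!all(ends %in% nodes$user_id)) {
      stop("edge endpoints missing from the node table")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "retweet_network")
}

#' @export
print.retweet_network <- function(x, ...) {
  cat("<retweet_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  if (nrow(x$nodes) > 0) {
    tab <- table(factor(x$nodes$label, levels = moral_foundations()))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Build the retweet network from a corpus and user profiles
#'
#' Every retweet event whose retweeter and original author both carry a
#' (non-excluded) foundation label adds 1 to the weight of the undirected
#' edge between them; retweet direction is discarded, so reciprocal
#' retweets accumulate on one weight. Nodes are exactly the endpoints of
#' retained edges. Events involving excluded or unprofiled users are
#' dropped.
#'
#' @param tweets Data frame of tweets with `user_id` and
#'   `retweet_of_user` (NA when the tweet is not a retweet). All ingested
#'   tweets qualify, not only moral ones.
#' @param profiles User profiles from [build_user_profiles()].
#' @param weighted When `FALSE`, all retained edges get weight 1 — a
#'   de-weighted variant that damps bursts of retweets of a single event.
#' @return A `retweet_network` (possibly empty).
#' @export
build_retweet_network <- function(tweets, profiles, weighted = TRUE) {
  tweets <- tibble::as_tibble(tweets)
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("user_id", "retweet_of_user") %in% names(tweets)),
            all(c("user_id", "label") %in% names(profiles)))
  lab <- profiles$label
  names(lab) <- as.character(profiles$user_id)
  lab <- lab[lab != EXCLUDED]

  src <- as.character(tweets$user_id)
  dst <- as.character(tweets$retweet_of_user)
  ok <- !is.na(dst) & dst != src & src %in% names(lab) & dst %in% names(lab)
  src <- src[ok]; dst <- dst[ok]
  if (length(src) == 0) {
    return(retweet_network(
      tibble::tibble(user_id = character(), label = character()),
      tibble::tibble(user_a = character(), user_b = character(),
                     weight = numeric())
    ))
  }
  a <- pmin(src, dst); b <- pmax(src, dst)
  agg <- stats::aggregate(list(weight = rep(1, length(a))),
                          by = list(user_a = a, user_b = b), FUN = sum)
  if (!weighted) agg$weight <- rep(1, nrow(agg))
  ids <- sort(unique(c(agg$user_a, agg$user_b)))
  nodes <- tibble::tibble(user_id = ids, label = unname(lab[ids]))
  retweet_network(nodes, agg)
}

# Long (doubled) incidence table: one row per edge endpoint, used by all
# homophily computations.
incidence_long <- function(network) {
  e <- network$edges
  tibble::tibble(
    node = c(e$user_a, e$user_b),
    other = c(e$user_b, e$user_a),
    weight = c(e$weight, e$weight)
  )
}

#' Homophily of a single node
#'
#' The weighted fraction of a node's incident edges connecting it to
#' same-labeled nodes: the total weight of incident edges whose other
#' endpoint shares the node's label, divided by the total weight of all
#' incident edges.
#'
#' @param network A `retweet_network`.
#' @param user_id Node identifier; must exist and have at least one
#'   incident edge.
#' @return A number in \[0, 1\].
#' @export
node_homophily <- function(network, user_id) {
  stopifnot(inherits(network, "retweet_network"))
  user_id <- as.character(user_id)
  if (!user_id %in% network$nodes$user_id) {
    stop("node not in the network: ", user_id)
  }
  inc <- incidence_long(network)
  inc <- inc[inc$node == user_id, , drop = FALSE]
  if (nrow(inc) == 0) {
    stop("node has no incident edges: ", user_id)
  }
  lab <- stats::setNames(network$nodes$label, network$nodes$user_id)
  same <- lab[inc$other] == lab[user_id]
  sum(inc$weight[same]) / sum(inc$weight)
}

#' Per-node and per-foundation homophily of a retweet network
#'
#' Computes each node's homophily (weighted same-label edge fraction) and
#' averages it, unweighted, over the nodes carrying each foundation label.
#' Foundations with no labeled node are absent from the result, not
#' reported as zero. Per-foundation scores above `threshold` are flagged
#' as homophilous.
#'
#' @param network A non-empty `retweet_network`.
#' @param threshold Flagging threshold for the `homophilous` column
#'   (default 0.5).
#' @return A list of class `homophily_result` with `per_node` (tibble:
#'   `user_id`, `label`, `h`) and `per_foundation` (tibble: `foundation`,
#'   `H`, `n_nodes`, `homophilous`).
#' @export
network_homophily <- function(network, threshold = 0.5) {
  stopifnot(inherits(network, "retweet_network"))
  if (nrow(network$nodes) == 0) stop("cannot compute homophily of an empty network")
  lab <- stats::setNames(network$nodes$label, network$nodes$user_id)
  h <- node_homophily_all(network, lab)
  per_node <- tibble::tibble(
    user_id = names(h), label = unname(lab[names(h)]), h = unname(h)
  )
  per_foundation <- foundation_means(per_node$h, per_node$label)
  per_foundation$homophilous <- per_foundation$H > threshold
  structure(list(per_node = per_node, per_foundation = per_foundation),
            class = "homophily_result")
}

# Vectorised h_i for all nodes with >= 1 incident edge, given a label map.
node_homophily_all <- function(network, lab) {
  inc <- incidence_long(network)
  if (nrow(inc) == 0) return(stats::setNames(numeric(0), character(0)))
  same <- lab[inc$other] == lab[inc$node]
  tot <- rowsum(inc$weight, inc$node)
  sm <- rowsum(inc$weight * same, inc$node)
  stats::setNames(as.numeric(sm) / as.numeric(tot), rownames(tot))
}

foundation_means <- function(h, labels) {
  present <- moral_foundations()[moral_foundations() %in% labels]
  tibble::tibble(
    foundation = present,
    H = vapply(present, function(f) mean(h[labels == f]), 0, USE.NAMES = FALSE),
    n_nodes = vapply(present, function(f) sum(labels == f), 0L, USE.NAMES = FALSE)
  )
}

#' @export
print.homophily_result <- function(x, ...) {
  cat("<homophily_result> ", nrow(x$per_node), " nodes\n", sep = "")
  print(x$per_foundation)
  invisible(x)
}

#' Label-permutation null distribution of per-foundation homophily
#'
#' Shuffles the node labels uniformly at random `n_perm` times, holding
#' the graph fixed, and recomputes the per-foundation homophily each time.
#' The null mean is the baseline against which observed scores (and the
#' conventional 0.5 threshold) can be judged: under random mixing a
#' foundation's expected homophily is roughly its label share among
#' network neighbours, not 0.5.
#'
#' @param network A non-empty `retweet_network`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `homophily_null` with `samples` (an
#'   `n_perm` x 5 matrix of null H values, columns in foundation order,
#'   `NA` for foundations with no nodes) and `summary` (tibble:
#'   `foundation`, `null_mean`, `null_sd`, `n_nodes`).
#' @export
permutation_null <- function(network, n_perm, seed = NULL) {
  stopifnot(inherits(network, "retweet_network"), n_perm >= 1)
  if (nrow(network$nodes) == 0) stop("cannot permute an empty network")
  fnd <- moral_foundations()
  ids <- network$nodes$user_id
  labels <- network$nodes$label
  samples <- matrix(NA_real_, nrow = n_perm, ncol = 5,
                    dimnames = list(NULL, fnd))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      shuffled <- stats::setNames(sample(labels), ids)
      h <- node_homophily_all(network, shuffled)
      pf <- foundation_means(h, unname(shuffled[names(h)]))
      samples[p, pf$foundation] <- pf$H
    }
  })
  present <- fnd[colSums(!is.na(samples)) > 0]
  summary <- tibble::tibble(
    foundation = present,
    null_mean = unname(colMeans(samples[, present, drop = FALSE], na.rm = TRUE)),
    null_sd = unname(apply(samples[, present, drop = FALSE], 2, stats::sd,
                           na.rm = TRUE)),
    n_nodes = vapply(present, function(f) sum(labels == f), 0L,
                     USE.NAMES = FALSE)
  )
  structure(list(samples = samples, summary = summary),
            class = "homophily_null")
}

#' Extract the k-core of a retweet network
#'
#' The maximal subnetwork in which every node has at least `k` incident
#' edges (unweighted degree), obtained by iteratively pruning lower-degree
#' nodes. Used to thin large networks for display export. The result may
#' be empty; `k = 0` returns the network unchanged.
#'
#' @param network A `retweet_network`.
#' @param k Non-negative integer.
#' @return A `retweet_network`.
#' @export
k_core <- function(network, k) {
  stopifnot(inherits(network, "retweet_network"), k >= 0)
  if (k == 0 || nrow(network$nodes) == 0) return(network)
  g <- as_igraph(network)
  core <- igraph::coreness(g)
  keep <- names(core)[core >= k]
  nodes <- network$nodes[network$nodes$user_id %in% keep, , drop = FALSE]
  edges <- network$edges[network$edges$user_a %in% keep &
                           network$edges$user_b %in% keep, , drop = FALSE]
  # nodes are defined as edge endpoints; pruning edges cannot strand a
  # k-core node for k >= 1, but guard anyway
  ends <- unique(c(edges$user_a, edges$user_b))
  nodes <- nodes[nodes$user_id %in% ends, , drop = FALSE]
  retweet_network(nodes, edges)
}

#' Convert a retweet network to an igraph graph
#'
#' Node labels become the `label` vertex attribute and weights the
#' `weight` edge attribute.
#'
#' @param network A `retweet_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "retweet_network"))
  igraph::graph_from_data_frame(
    d = network$edges[, c("user_a", "user_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$user_id,
                          label = network$nodes$label,
                          stringsAsFactors = FALSE)
  )
}

#' Write a network edge list as TSV
#'
#' Columns `user_a`, `user_b`, `weight`, tab-separated with a header.
#'
#' @param network A `retweet_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(network, path) {
  stopifnot(inherits(network, "retweet_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a retweet network as GEXF
#'
#' Minimal GEXF 1.2 with the moral label as a node attribute and edge
#' weights, for loading into external graph-visualization tools.
#'
#' @param network A `retweet_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(network, path) {
  stopifnot(inherits(network, "retweet_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  n <- network$nodes; e <- network$edges
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="moral_label" type="string"/>',
    '    </attributes>',
    '    <nodes>',
    sprintf('      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/></attvalues></node>',
            esc(n$user_id), esc(n$user_id), esc(n$label)),
    '    </nodes>',
    '    <edges>',
    if (nrow(e) > 0) sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
                             seq_len(nrow(e)) - 1L, esc(e$user_a), esc(e$user_b),
                             format(e$weight)) else character(0),
    '    </edges>',
    '  </graph>',
    '</gexf>'
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
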