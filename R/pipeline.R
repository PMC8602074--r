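#' Run the full moral-analysis pipeline
#'
#' Orchestrates scoring, user profiling, retweet-network homophily,
#' valence stratification and (with two corpora) corpus comparison from a
#' single configuration, writing per-stage outputs and a run manifest to
#' an output directory. Any stage failure aborts with the failing stage
#' named.
#'
#' The configuration is a named list (or a path to a JSON file) with:
#' \describe{
#'   \item{corpora}{named list: corpus key -> path (JSONL/CSV) or data
#'     frame.}
#'   \item{lexicons}{named list: corpus key -> `.dic` path or
#'     `moral_lexicon`. A single unnamed lexicon is shared by all
#'     corpora.}
#'   \item{valence_lexicons}{optional; corpus key -> two-column TSV path
#'     or named numeric vector.}
#'   \item{count}{`"occurrences"` (default) or `"types"`.}
#'   \item{weighted}{weighted retweet edges (default `TRUE`).}
#'   \item{include_retweets}{count retweets toward profiles (default
#'     `TRUE`).}
#'   \item{kcore}{report homophily on the k-core with this k (default 0 =
#'     whole network).}
#'   \item{n_perm}{label-permutation null draws (default 0 = skip).}
#'   \item{seed}{seed for the permutation null.}
#'   \item{pca_standardize}{standardize before PCA (default `FALSE`).}
#'   \item{out_dir}{output directory (created if missing).}
#' }
#'
#' @param config Named list or path to a JSON config file.
#' @return The run manifest (also written to `manifest.json`), invisibly:
#'   package version, configuration, input digests, and per-stage record
#'   counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config), !is.null(config$corpora),
            !is.null(config$lexicons), !is.null(config$out_dir))
  cfg <- utils::modifyList(
    list(count = "occurrences", weighted = TRUE, include_retweets = TRUE,
         kcore = 0, n_perm = 0, seed = NULL, pca_standardize = FALSE,
         valence_lexicons = NULL),
    config
  )
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  digest_input <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      list(path = x, md5 = unname(tools::md5sum(x)),
           bytes = file.size(x))
    } else {
      list(path = NA, md5 = NA, bytes = NA)
    }
  }

  keys <- names(cfg$corpora)
  if (is.null(keys)) keys <- paste0("corpus", seq_along(cfg$corpora))
  manifest <- list(
    package = "moralnet",
    version = as.character(utils::packageVersion("moralnet")),
    created = format(Sys.time(), tz = "UTC"),
    config = cfg[setdiff(names(cfg), c("corpora", "lexicons",
                                       "valence_lexicons"))],
    inputs = list(),
    stages = list()
  )

  get_lexicon <- function(key) {
    lx <- if (!is.null(cfg$lexicons[[key]])) cfg$lexicons[[key]] else
      cfg$lexicons[[1]]
    if (inherits(lx, "moral_lexicon")) lx else parse_liwc_dic(lx)
  }
  get_vlex <- function(key) {
    if (is.null(cfg$valence_lexicons)) return(NULL)
    vl <- if (!is.null(cfg$valence_lexicons[[key]])) cfg$valence_lexicons[[key]]
      else cfg$valence_lexicons[[1]]
    if (is.null(vl)) return(NULL)
    if (is.numeric(vl)) vl else read_valence_lexicon(vl)
  }

  all_loadings <- list()
  for (key in keys) {
    src <- cfg$corpora[[key]]
    manifest$inputs[[key]] <- digest_input(src)
    tweets <- run_stage(paste0(key, ":read"), {
      if (is.character(src) && length(src) == 1L) read_corpus(src)
      else tibble::as_tibble(src)
    })
    counts <- list(tweets_read = nrow(tweets))

    loadings <- run_stage(paste0(key, ":score"), {
      if (nrow(tweets) == 0) stop("corpus is empty")
      lx <- get_lexicon(key)
      filter_moral_corpus(tweets, lx, count = cfg$count)
    })
    counts$tweets_moral <- nrow(loadings)
    counts$tweets_filtered <- counts$tweets_read - nrow(loadings)
    utils::write.csv(loadings, file.path(out_dir, paste0(key, "_loadings.csv")),
                     row.names = FALSE)
    all_loadings[[key]] <- loadings

    profiles <- run_stage(paste0(key, ":profile"), {
      build_user_profiles(loadings, include_retweets = cfg$include_retweets)
    })
    counts$users_total <- nrow(profiles)
    counts$users_excluded <- sum(profiles$label == EXCLUDED)
    utils::write.csv(profiles, file.path(out_dir, paste0(key, "_users.csv")),
                     row.names = FALSE)

    run_stage(paste0(key, ":network"), {
      net <- build_retweet_network(tweets, profiles,
                                   weighted = cfg$weighted)
      if (cfg$kcore > 0) net <- k_core(net, cfg$kcore)
      counts$nodes <- nrow(net$nodes)
      counts$edges <- nrow(net$edges)
      if (nrow(net$nodes) > 0) {
        hom <- network_homophily(net)
        res <- lapply(seq_len(nrow(hom$per_foundation)), function(i) {
          r <- hom$per_foundation[i, ]
          list(H = r$H, n_nodes = r$n_nodes, homophilous = r$homophilous)
        })
        names(res) <- hom$per_foundation$foundation
        if (cfg$n_perm > 0) {
          null <- permutation_null(net, cfg$n_perm,
                                   seed = derive_seed(cfg$seed, match(key, keys)))
          for (i in seq_len(nrow(null$summary))) {
            f <- null$summary$foundation[i]
            if (!is.null(res[[f]])) {
              res[[f]]$null_mean <- null$summary$null_mean[i]
              res[[f]]$null_sd <- null$summary$null_sd[i]
            }
          }
        }
        jsonlite::write_json(res, file.path(out_dir, paste0(key, "_homophily.json")),
                             auto_unbox = TRUE, digits = NA)
        write_edgelist_tsv(net, file.path(out_dir, paste0(key, "_edges.tsv")))
        write_gexf(net, file.path(out_dir, paste0(key, "_network.gexf")))
      }
    })

    vlex <- get_vlex(key)
    if (!is.null(vlex)) {
      run_stage(paste0(key, ":valence"), {
        moral_ids <- loadings$tweet_id
        moral_tweets <- tweets[as.character(tweets$tweet_id) %in% moral_ids, ,
                               drop = FALSE]
        vres <- score_corpus_valence(moral_tweets, lexicon = vlex)
        vtab <- valence_by_foundation(loadings, vres)
        utils::write.csv(vtab, file.path(out_dir, paste0(key, "_valence.csv")),
                         row.names = FALSE)
        counts$tweets_valenced <- nrow(vres)
      })
    }
    manifest$stages[[key]] <- counts
  }

  if (length(keys) == 2) {
    run_stage("compare", {
      cmp <- compare_corpora(all_loadings[[keys[1]]], all_loadings[[keys[2]]],
                             standardize = cfg$pca_standardize)
      kw <- cmp$kruskal_wallis
      kw_json <- lapply(seq_len(nrow(kw)), function(i) {
        list(statistic = kw$statistic[i], p = kw$p_value[i])
      })
      names(kw_json) <- kw$dimension
      jsonlite::write_json(kw_json, file.path(out_dir, "compare_kw.json"),
                           auto_unbox = TRUE, digits = NA)
      for (i in 1:2) {
        p <- cmp[[paste0("pca_", letters[i])]]
        prefix <- file.path(out_dir, paste0("pca_", keys[i]))
        utils::write.csv(
          data.frame(component = seq_along(p$variance_explained),
                     variance_explained = p$variance_explained),
          paste0(prefix, "_scree.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(p$loadings),
                         paste0(prefix, "_loadings.csv"), row.names = TRUE)
        utils::write.csv(as.data.frame(p$scores),
                         paste0(prefix, "_scores.csv"), row.names = FALSE)
      }
      manifest$stages$compare <- list(dimensions_tested = nrow(kw))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
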