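#' Aggregate labeled tweets into per-user moral profiles
#'
#' For each user, the proportion for foundation j is the number of their
#' moral tweets labeled j divided by their total number of moral tweets. A
#' multi-labeled tweet counts once toward each of its foundations (so the
#' proportions can sum to more than 1), but counts once in the total. A
#' user is labeled with the foundation of maximum proportion; users with a
#' tied maximum, or with fewer than two moral tweets, are marked
#' `EXCLUDED`. Ties are detected on integer tweet counts.
#'
#' @param labeled A data frame of labeled tweets as returned by
#'   [filter_moral_corpus()]: needs `user_id` and `labels` (pipe-joined
#'   foundations, or a list column of character vectors).
#' @param include_retweets Count retweeted posts toward the retweeting
#'   user's profile (default `TRUE`); requires a `retweet_of_user` column
#'   to distinguish them when `FALSE`.
#' @return A tibble with one row per user: `user_id`, `mp_care` ..
#'   `mp_purity`, `n_moral_tweets`, `label` (a foundation or
#'   `"EXCLUDED"`). All users are returned, including excluded ones.
#' @export
build_user_profiles <- function(labeled, include_retweets = TRUE) {
  labeled <- tibble::as_tibble(labeled)
  stopifnot(all(c("user_id", "labels") %in% names(labeled)))
  if (!include_retweets) {
    if (!"retweet_of_user" %in% names(labeled)) {
      stop("include_retweets = FALSE requires a 'retweet_of_user' column")
    }
    labeled <- labeled[is.na(labeled$retweet_of_user), , drop = FALSE]
  }
  fnd <- moral_foundations()
  lab_list <- if (is.list(labeled$labels)) labeled$labels else
    split_labels(labeled$labels)

  users <- sort(unique(as.character(labeled$user_id)))
  if (length(users) == 0) {
    return(tibble::tibble(
      user_id = character(), mp_care = numeric(), mp_fairness = numeric(),
      mp_ingroup = numeric(), mp_authority = numeric(), mp_purity = numeric(),
      n_moral_tweets = integer(), label = character()
    ))
  }
  long <- tibble::tibble(
    user_id = rep(as.character(labeled$user_id), lengths(lab_list)),
    label = unlist(lab_list, use.names = FALSE)
  )
  stopifnot(all(long$label %in% fnd))
  counts <- table(factor(long$user_id, levels = users),
                  factor(long$label, levels = fnd))
  counts <- matrix(as.integer(counts), nrow = length(users),
                   dimnames = list(users, fnd))
  n_tweets <- as.integer(table(factor(as.character(labeled$user_id),
                                      levels = users)))
  mp <- counts / n_tweets
  label <- vapply(seq_along(users), function(i) {
    label_user(counts[i, ], n_tweets[i])
  }, "")
  tibble::tibble(
    user_id = users,
    mp_care = mp[, "CARE"],
    mp_fairness = mp[, "FAIRNESS"],
    mp_ingroup = mp[, "INGROUP"],
    mp_authority = mp[, "AUTHORITY"],
    mp_purity = mp[, "PURITY"],
    n_moral_tweets = n_tweets,
    label = label
  )
}

#' Label a user from their per-foundation tweet counts
#'
#' The user's label is the foundation attaining the maximum tweet count.
#' If the maximum is tied between foundations, or the user has fewer than
#' two moral tweets, the user is `EXCLUDED` from network analysis.
#'
#' @param counts Named integer vector of per-foundation labeled-tweet
#'   counts, in [moral_foundations()] order.
#' @param n_moral_tweets The user's total number of moral tweets.
#' @return A foundation name, or `"EXCLUDED"`.
#' @export
label_user <- function(counts, n_moral_tweets) {
  if (n_moral_tweets < 2) return(EXCLUDED)
  top <- which(counts == max(counts))
  if (length(top) != 1) return(EXCLUDED)
  moral_foundations()[top]
}
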