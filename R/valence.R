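#' Read a valence lexicon from a two-column TSV
#'
#' Each line holds a lowercase term and a polarity in \[-1, 1\],
#' tab-separated. Used by the default valence scorer.
#'
#' @param path TSV file path (no header).
#' @return Named numeric vector of polarities.
#' @export
read_valence_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("term", "polarity"),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  pol <- as.numeric(df$polarity)
  if (anyNA(pol) || any(pol < -1 | pol > 1)) {
    stop("valence polarities must be numbers in [-1, 1]")
  }
  stats::setNames(pol, tolower(df$term))
}

#' Score the emotional valence of a tokenized tweet
#'
#' The default scorer returns the mean polarity of the tokens found in the
#' valence lexicon, and 0 when none match — a transparent stand-in
#' honouring the same contract as external sentiment tools (scores in
#' \[-1, 1\]). A custom scorer (e.g. an adapter around VADER for English or
#' oseti for Japanese) can be plugged in wherever a scorer argument is
#' accepted; it must map a token vector to one number in \[-1, 1\].
#'
#' @param tokens Character vector of lowercase tokens.
#' @param lexicon Named numeric vector (term -> polarity in \[-1, 1\]).
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' score_valence(c("good", "day"), c(good = 0.8))
score_valence <- function(tokens, lexicon) {
  hits <- lexicon[tokens[tokens %in% names(lexicon)]]
  if (length(hits) == 0) return(0)
  mean(hits)
}

#' Classify a valence score as positive, negative or neutral
#'
#' Strict sign thresholds: scores above 0 are positive, below 0 negative,
#' exactly 0 neutral.
#'
#' @param score A number in \[-1, 1\].
#' @return `"POSITIVE"`, `"NEGATIVE"` or `"NEUTRAL"`.
#' @export
classify_valence <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < -1 || score > 1) {
    stop("valence score must be a single number in [-1, 1]")
  }
  if (score > 0) "POSITIVE" else if (score < 0) "NEGATIVE" else "NEUTRAL"
}

#' Score valence for a whole corpus
#'
#' Applies a valence scorer to each tweet's tokens and classifies the
#' result.
#'
#' @param corpus Data frame of tweets (`tweet_id` plus `text` or `tokens`;
#'   see [filter_moral_corpus()]).
#' @param lexicon Named numeric valence lexicon (ignored when `scorer` is
#'   given).
#' @param scorer Optional function `tokens -> score in [-1, 1]` replacing
#'   the default lexicon-mean scorer.
#' @param stopwords,segmenter Passed to [tokenize()] for raw text.
#' @return Tibble with `tweet_id`, `score`, `klass`.
#' @export
score_corpus_valence <- function(corpus, lexicon = NULL, scorer = NULL,
                                 stopwords = NULL, segmenter = NULL) {
  corpus <- tibble::as_tibble(corpus)
  stopifnot("tweet_id" %in% names(corpus))
  if (is.null(scorer)) {
    if (is.null(lexicon)) stop("either a valence lexicon or a scorer is required")
    scorer <- function(tokens) score_valence(tokens, lexicon)
  }
  toks <- corpus_tokens(corpus, stopwords = stopwords, segmenter = segmenter)
  score <- vapply(toks, scorer, 0)
  tibble::tibble(
    tweet_id = as.character(corpus$tweet_id),
    score = score,
    klass = vapply(score, classify_valence, "")
  )
}

#' Valence class percentages per moral foundation
#'
#' For each foundation, the percentage of its tweets classified positive,
#' negative and neutral. A tweet labeled with several foundations counts
#' under each of them. Foundations with no tweets are absent from the
#' table. Each row sums to 100 (up to floating-point rounding).
#'
#' @param labeled Labeled tweets from [filter_moral_corpus()] (`tweet_id`,
#'   `labels`).
#' @param valence Valence results from [score_corpus_valence()]
#'   (`tweet_id`, `klass`); every labeled tweet must have one.
#' @return Tibble with `foundation`, `pct_positive`, `pct_negative`,
#'   `pct_neutral`, `n_tweets`.
#' @export
valence_by_foundation <- function(labeled, valence) {
  labeled <- tibble::as_tibble(labeled)
  valence <- tibble::as_tibble(valence)
  stopifnot(all(c("tweet_id", "labels") %in% names(labeled)),
            all(c("tweet_id", "klass") %in% names(valence)))
  klass <- stats::setNames(valence$klass, as.character(valence$tweet_id))
  ids <- as.character(labeled$tweet_id)
  if (!all(ids %in% names(klass))) {
    stop("every labeled tweet needs a valence result")
  }
  lab_list <- if (is.list(labeled$labels)) labeled$labels else
    split_labels(labeled$labels)
  long <- tibble::tibble(
    foundation = unlist(lab_list, use.names = FALSE),
    klass = rep(unname(klass[ids]), lengths(lab_list))
  )
  present <- moral_foundations()[moral_foundations() %in% long$foundation]
  rows <- lapply(present, function(f) {
    k <- long$klass[long$foundation == f]
    n <- length(k)
    tibble::tibble(
      foundation = f,
      pct_positive = 100 * sum(k == "POSITIVE") / n,
      pct_negative = 100 * sum(k == "NEGATIVE") / n,
      pct_neutral = 100 * sum(k == "NEUTRAL") / n,
      n_tweets = n
    )
  })
  dplyr::bind_rows(rows)
}
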