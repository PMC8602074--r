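# A small default English stop list; the choice of list is configurable in
# tokenize() because results are mildly sensitive to it.
DEFAULT_STOPWORDS_EN <- c(
  "a", "an", "the", "is", "are", "was", "were", "be", "been", "being",
  "am", "do", "does", "did", "have", "has", "had", "will", "would",
  "can", "could", "should", "shall", "may", "might", "must",
  "i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
  "us", "them", "my", "your", "his", "its", "our", "their",
  "this", "that", "these", "those", "and", "or", "but", "if", "so",
  "to", "of", "in", "on", "at", "by", "for", "with", "as", "from",
  "not", "no", "nor", "what", "which", "who", "whom", "there", "here",
  "when", "where", "why", "how", "then", "than", "too", "very", "rt"
)

#' Tokenize a tweet
#'
#' Strips URLs, @-mentions and `#` symbols (keeping the tag word), removes
#' punctuation, lowercases, and splits into tokens. English text is split
#' on whitespace with stop words removed. Japanese text goes through a
#' pluggable morphological segmenter; when none is supplied, a naive
#' fallback splits at boundaries between character classes (kanji,
#' hiragana, katakana, latin, digits) so the pipeline runs without external
#' tooling — real analyses should plug in a proper segmenter.
#'
#' @param text A character scalar (any unicode string).
#' @param language `"en"` or `"ja"`.
#' @param stopwords Character vector of tokens to drop after splitting.
#'   Defaults to a small built-in English list for `"en"` and to none for
#'   `"ja"`.
#' @param segmenter Optional function `character -> character vector` used
#'   to segment Japanese text (e.g. a MeCab binding).
#' @return Character vector of lowercase tokens (possibly empty).
#' @export
#' @examples
#' tokenize("Killing is #immoral http://t.co/x", "en")
tokenize <- function(text, language = c("en", "ja"), stopwords = NULL,
                     segmenter = NULL) {
  language <- match.arg(language)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(stopwords)) {
    stopwords <- if (language == "en") DEFAULT_STOPWORDS_EN else character(0)
  }
  x <- text
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x, perl = TRUE)
  x <- gsub("@\\w+", " ", x, perl = TRUE)
  x <- gsub("#", "", x, fixed = TRUE)

  if (language == "en") {
    x <- tolower(x)
    x <- gsub("[^\\p{L}\\p{N}']+", " ", x, perl = TRUE)
    toks <- strsplit(trimws(x), "\\s+")[[1]]
  } else {
    if (!is.null(segmenter)) {
      toks <- tolower(segmenter(x))
    } else {
      toks <- segment_ja_naive(x)
    }
  }
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% stopwords)]
}

# Fallback Japanese segmentation: split at transitions between unicode
# character classes. Not a morphological analysis; adequate for synthetic
# fixtures and rough exploration only.
segment_ja_naive <- function(x) {
  x <- gsub("[[:punct:][:space:]　-〿！-／：-＠［-｀｛-･]+",
            " ", x, perl = TRUE)
  chars <- strsplit(x, "")[[1]]
  if (length(chars) == 0) return(character(0))
  cls <- vapply(chars, char_class_ja, "")
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  toks <- vapply(seq_along(starts), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, "")
  toks <- tolower(trimws(toks[runs$values != "other"]))
  toks[nzchar(toks)]
}

char_class_ja <- function(ch) {
  cp <- utf8ToInt(ch)
  if (cp >= 0x3040 && cp <= 0x309f) return("hiragana")
  if (cp >= 0x30a0 && cp <= 0x30ff) return("katakana")
  if ((cp >= 0x4e00 && cp <= 0x9fff) || (cp >= 0x3400 && cp <= 0x4dbf)) return("kanji")
  if (grepl("[A-Za-z']", ch)) return("latin")
  if (grepl("[0-9]", ch)) return("digit")
  "other"
}

#' Compute a tweet's moral-loading vector
#'
#' For each foundation j, the loading is the number of token occurrences
#' matching any dictionary category (virtue or vice) of foundation j,
#' divided by the number of occurrences matching at least one of the five
#' foundations. GENERAL (general-morality) matches are excluded from both
#' numerator and denominator. With `count = "types"` distinct token types
#' are counted instead of occurrences.
#'
#' A tweet with no moral matches has an undefined loading
#' (`n_moral_tokens = 0`, all-`NA` vector) and is dropped by
#' [filter_moral_corpus()].
#'
#' @param tokens Character vector of lowercase tokens.
#' @param lexicon A `moral_lexicon`.
#' @param count `"occurrences"` (default; repeated moral words weigh more,
#'   the standard LIWC convention) or `"types"`.
#' @return A list with `ml` (named numeric of length 5 over
#'   [moral_foundations()], `NA` when undefined), `counts` (named integer
#'   numerators), and `n_moral_tokens` (the shared denominator).
#' @export
#' @examples
#' lex <- parse_liwc_dic(c("%", "01\tHarmVice", "02\tFairnessVirtue",
#'                         "03\tIngroupVirtue", "%",
#'                         "kill\t01", "fair\t02", "loyal\t03"))
#' moral_loading(c("kill", "fair", "loyal", "fair"), lex)$ml
moral_loading <- function(tokens, lexicon,
                          count = c("occurrences", "types")) {
  count <- match.arg(count)
  stopifnot(inherits(lexicon, "moral_lexicon"))
  fnd <- moral_foundations()
  if (count == "types") tokens <- unique(tokens)
  sets <- token_foundation_sets(lexicon, tokens)
  per_token <- sets[tokens]
  counts <- stats::setNames(integer(5), fnd)
  for (s in per_token) {
    if (length(s) > 0) counts[s] <- counts[s] + 1L
  }
  denom <- sum(lengths(per_token) > 0)
  if (denom == 0) {
    ml <- stats::setNames(rep(NA_real_, 5), fnd)
  } else {
    ml <- counts / denom
  }
  list(ml = ml, counts = counts, n_moral_tokens = as.integer(denom))
}

#' Label a tweet with its dominant moral foundation(s)
#'
#' Returns the full argmax set of the loading vector. Ties are detected on
#' the exact integer numerators (all components share one denominator), so
#' no floating-point tie-breaking artifacts arise. A tweet whose maximum is
#' attained by several foundations carries all of them.
#'
#' @param loading A loading as returned by [moral_loading()]; must be
#'   defined (`n_moral_tokens > 0`).
#' @return Character vector of foundations (length >= 1).
#' @export
label_tweet <- function(loading) {
  if (is.null(loading$n_moral_tokens) || loading$n_moral_tokens == 0) {
    stop("cannot label a tweet with an undefined moral loading (no moral tokens)")
  }
  counts <- loading$counts
  names(counts)[counts == max(counts) & counts > 0]
}

#' Score and filter a tweet corpus
#'
#' Computes moral loadings for every tweet and keeps those with at least
#' one moral-dictionary match, preserving input order. The number of
#' discarded tweets is reported with a message.
#'
#' @param corpus A data frame of tweets with columns `tweet_id`, `user_id`,
#'   and either `text` (character) or `tokens` (list of character vectors);
#'   optional `lang` (`"en"`/`"ja"`, default `"en"`) and `retweet_of_user`.
#'   When both `text` and `tokens` are present, `tokens` wins.
#' @param lexicon A `moral_lexicon`.
#' @param count Passed to [moral_loading()].
#' @param stopwords,segmenter Passed to [tokenize()] when tokenizing raw
#'   text.
#' @return A tibble with one row per retained tweet: `tweet_id`,
#'   `user_id`, `retweet_of_user`, the five loading columns `ml_care`,
#'   `ml_fairness`, `ml_ingroup`, `ml_authority`, `ml_purity`,
#'   `n_moral_tokens`, and `labels` (foundations joined with `"|"`).
#' @export
filter_moral_corpus <- function(corpus, lexicon,
                                count = c("occurrences", "types"),
                                stopwords = NULL, segmenter = NULL) {
  count <- match.arg(count)
  stopifnot(inherits(lexicon, "moral_lexicon"))
  corpus <- tibble::as_tibble(corpus)
  stopifnot(all(c("tweet_id", "user_id") %in% names(corpus)))
  n <- nrow(corpus)
  if (!"retweet_of_user" %in% names(corpus)) {
    corpus$retweet_of_user <- rep(NA_character_, n)
  }
  # self-retweets are dropped at ingest
  self_rt <- !is.na(corpus$retweet_of_user) &
    corpus$retweet_of_user == corpus$user_id
  corpus$retweet_of_user[self_rt] <- NA_character_

  tok_list <- corpus_tokens(corpus, stopwords = stopwords,
                            segmenter = segmenter)

  # match each distinct token in the corpus once
  all_sets <- token_foundation_sets(lexicon, unlist(tok_list, use.names = FALSE))
  fnd <- moral_foundations()

  score_one <- function(toks) {
    if (count == "types") toks <- unique(toks)
    per <- all_sets[toks]
    counts <- stats::setNames(integer(5), fnd)
    for (s in per) if (length(s) > 0) counts[s] <- counts[s] + 1L
    denom <- sum(lengths(per) > 0)
    c(counts, n = denom)
  }
  if (n > 0) {
    mat <- t(vapply(tok_list, score_one, numeric(6)))
  } else {
    mat <- matrix(numeric(0), ncol = 6,
                  dimnames = list(NULL, c(fnd, "n")))
  }
  denom <- mat[, "n"]
  keep <- denom > 0
  message(sum(!keep), " of ", n, " tweets had no moral-dictionary match and were filtered")

  counts_kept <- mat[keep, fnd, drop = FALSE]
  denom_kept <- denom[keep]
  ml <- counts_kept / denom_kept
  labels <- vapply(seq_len(sum(keep)), function(i) {
    ci <- counts_kept[i, ]
    paste(fnd[ci == max(ci) & ci > 0], collapse = "|")
  }, "")
  out <- tibble::tibble(
    tweet_id = as.character(corpus$tweet_id[keep]),
    user_id = as.character(corpus$user_id[keep]),
    retweet_of_user = as.character(corpus$retweet_of_user[keep]),
    ml_care = ml[, "CARE"],
    ml_fairness = ml[, "FAIRNESS"],
    ml_ingroup = ml[, "INGROUP"],
    ml_authority = ml[, "AUTHORITY"],
    ml_purity = ml[, "PURITY"],
    n_moral_tokens = as.integer(denom_kept),
    labels = labels
  )
  out
}

# Resolve the token list for each corpus row: a `tokens` list column wins,
# otherwise `text` is tokenized per the row's language.
corpus_tokens <- function(corpus, stopwords = NULL, segmenter = NULL) {
  n <- nrow(corpus)
  lang <- if ("lang" %in% names(corpus)) as.character(corpus$lang) else rep("en", n)
  lang[is.na(lang)] <- "en"
  has_tokens <- "tokens" %in% names(corpus)
  has_text <- "text" %in% names(corpus)
  if (!has_tokens && !has_text) {
    stop("corpus must have a 'text' or a 'tokens' column")
  }
  lapply(seq_len(n), function(i) {
    if (has_tokens && !is.null(corpus$tokens[[i]]) &&
        !all(is.na(corpus$tokens[[i]]))) {
      tolower(as.character(corpus$tokens[[i]]))
    } else if (has_text && !is.na(corpus$text[i])) {
      tokenize(corpus$text[i], language = lang[i], stopwords = stopwords,
               segmenter = segmenter)
    } else {
      character(0)
    }
  })
}

# Split pipe-joined label strings back into character vectors.
split_labels <- function(labels) {
  strsplit(labels, "|", fixed = TRUE)
}
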