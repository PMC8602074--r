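#' Read a tweet corpus from JSONL or CSV
#'
#' JSONL files hold one JSON object per line with fields `id` (or
#' `tweet_id`), `user_id`, `text` or `tokens` (array), and optionally
#' `lang` and `retweet_of_user`. CSV files use the same column names
#' (without a `tokens` column). Self-retweets are dropped by the scoring
#' step.
#'
#' @param path File path; format chosen by extension (`.jsonl`/`.json`
#'   vs `.csv`).
#' @return A tibble with columns `tweet_id`, `user_id`, `text`, `tokens`,
#'   `lang`, `retweet_of_user`.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    get_chr <- function(r, keys) {
      for (k in keys) if (!is.null(r[[k]]) && !all(is.na(r[[k]]))) {
        return(as.character(r[[k]])[1])
      }
      NA_character_
    }
    tibble::tibble(
      tweet_id = vapply(recs, get_chr, "", keys = c("tweet_id", "id")),
      user_id = vapply(recs, get_chr, "", keys = "user_id"),
      text = vapply(recs, get_chr, "", keys = "text"),
      tokens = lapply(recs, function(r) {
        if (is.null(r$tokens)) NULL else as.character(r$tokens)
      }),
      lang = vapply(recs, get_chr, "", keys = "lang"),
      retweet_of_user = vapply(recs, get_chr, "", keys = "retweet_of_user")
    )
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = "character")
    if ("id" %in% names(df) && !"tweet_id" %in% names(df)) {
      names(df)[names(df) == "id"] <- "tweet_id"
    }
    for (col in c("text", "lang", "retweet_of_user")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
      df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
    }
    tibble::as_tibble(df)
  } else {
    stop("unsupported corpus format: ", path)
  }
}

#' Write a tweet corpus as JSONL
#'
#' One JSON object per line with fields `id`, `user_id`, `tokens` or
#' `text`, `lang`, and `retweet_of_user` when present.
#'
#' @param tweets Corpus tibble (see [read_corpus()] / [generate_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(tweets, path) {
  tweets <- tibble::as_tibble(tweets)
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    rec <- list(id = tweets$tweet_id[i], user_id = tweets$user_id[i])
    if ("tokens" %in% names(tweets) && !is.null(tweets$tokens[[i]])) {
      rec$tokens <- as.list(tweets$tokens[[i]])
    } else if ("text" %in% names(tweets) && !is.na(tweets$text[i])) {
      rec$text <- tweets$text[i]
    }
    if ("lang" %in% names(tweets) && !is.na(tweets$lang[i])) {
      rec$lang <- tweets$lang[i]
    }
    if ("retweet_of_user" %in% names(tweets) &&
        !is.na(tweets$retweet_of_user[i])) {
      rec$retweet_of_user <- tweets$retweet_of_user[i]
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
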