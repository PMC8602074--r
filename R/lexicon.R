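#' Construct a moral lexicon object
#'
#' Low-level constructor used by [parse_liwc_dic()] and
#' [generate_lexicon()]. Validates the category table and entry list and
#' returns a `moral_lexicon`.
#'
#' @param name Character scalar naming the lexicon.
#' @param categories A data frame with columns `id` (integer), `name`
#'   (character), `foundation` (one of [moral_foundations()] or
#'   `"GENERAL"`), `polarity` (`"VIRTUE"`, `"VICE"` or `"NONE"`).
#' @param entries A data frame with columns `pattern` (lowercase character,
#'   no whitespace, no trailing `*`), `is_stem` (logical) and `categories`
#'   (list column of integer category ids, each non-empty).
#' @return An object of class `moral_lexicon`.
#' @export
moral_lexicon <- function(name, categories, entries) {
  categories <- tibble::as_tibble(categories)
  entries <- tibble::as_tibble(entries)
  stopifnot(
    all(c("id", "name", "foundation", "polarity") %in% names(categories)),
    all(c("pattern", "is_stem", "categories") %in% names(entries))
  )
  categories$id <- as.integer(categories$id)
  if (anyDuplicated(categories$id)) {
    stop("duplicate category ids: ",
         paste(unique(categories$id[duplicated(categories$id)]), collapse = ", "))
  }
  bad_pol <- categories$foundation == "GENERAL" & categories$polarity != "NONE"
  if (any(bad_pol)) {
    stop("GENERAL categories must have polarity NONE: ",
         paste(categories$name[bad_pol], collapse = ", "))
  }
  if (nrow(entries) > 0) {
    if (any(lengths(entries$categories) == 0)) {
      stop("entries with empty category sets: ",
           paste(entries$pattern[lengths(entries$categories) == 0], collapse = ", "))
    }
    if (any(grepl("\\s", entries$pattern)) || any(grepl("\\*$", entries$pattern))) {
      stop("entry patterns must contain no whitespace and no trailing '*'")
    }
    key <- paste0(entries$pattern, "\r", entries$is_stem)
    if (anyDuplicated(key)) {
      dups <- unique(entries$pattern[duplicated(key)])
      stop("duplicate dictionary entries: ", paste(dups, collapse = ", "))
    }
    refd <- unique(unlist(entries$categories))
    missing_ids <- setdiff(refd, categories$id)
    if (length(missing_ids) > 0) {
      stop("entries reference undeclared category ids: ",
           paste(missing_ids, collapse = ", "))
    }
    entries$categories <- lapply(entries$categories, as.integer)
  }
  structure(
    list(name = name, categories = categories, entries = entries),
    class = "moral_lexicon"
  )
}

#' Parse a LIWC-format moral foundations dictionary
#'
#' Reads the `.dic` dialect used by the moral foundations dictionaries: a
#' header block delimited by two lines consisting of `%`, with one
#' `id<TAB>name` pair per line, followed by body lines
#' `term<TAB>id[<TAB>id...]`. Terms ending in `*` are prefix stems (the `*`
#' is stripped and recorded in `is_stem`). Fields may be separated by tabs
#' or runs of spaces. Each category name is mapped to a foundation and a
#' polarity by case-insensitive substring matching (harm/care, fairness,
#' ingroup, authority, purity, virtue, vice; anything else is GENERAL).
#'
#' @param x Path to a `.dic` file, or a character vector of its lines, or a
#'   single string containing the whole file.
#' @param name Lexicon name; defaults to the file name or `"lexicon"`.
#' @return A `moral_lexicon`.
#' @export
#' @examples
#' dic <- c("%", "01\tHarmVirtue", "02\tHarmVice", "%",
#'          "kill\t02", "killer*\t02")
#' lex <- parse_liwc_dic(dic)
#' match_token(lex, "killers")
parse_liwc_dic <- function(x, name = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(name)) name <- basename(x)
    lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    if (length(x) == 1) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
    lines <- x
  }
  if (is.null(name)) name <- "lexicon"
  lines <- sub("\r$", "", lines)

  delim <- which(trimws(lines) == "%")
  if (length(delim) < 2) {
    stop("malformed header: expected two '%' delimiter lines, found ",
         length(delim))
  }
  header_lines <- lines[seq(delim[1] + 1L, length.out = delim[2] - delim[1] - 1L)]
  body_lines <- if (delim[2] < length(lines)) lines[(delim[2] + 1L):length(lines)] else character(0)

  parse_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

  cats <- list()
  for (i in seq_along(header_lines)) {
    line <- header_lines[i]
    if (!nzchar(trimws(line))) next
    f <- parse_fields(line)
    id <- suppressWarnings(as.integer(f[1]))
    if (length(f) < 2 || is.na(id)) {
      stop("malformed header line ", delim[1] + i, ": '", line, "'")
    }
    cname <- f[2]
    cats[[length(cats) + 1L]] <- tibble::tibble(
      id = id, name = cname,
      foundation = foundation_from_category_name(cname),
      polarity = polarity_from_category_name(cname)
    )
  }
  categories <- if (length(cats)) dplyr::bind_rows(cats) else
    tibble::tibble(id = integer(), name = character(),
                   foundation = character(), polarity = character())
  categories$polarity[categories$foundation == "GENERAL"] <- "NONE"

  pats <- character(0); stems <- logical(0); catsets <- list()
  for (i in seq_along(body_lines)) {
    line <- body_lines[i]
    if (!nzchar(trimws(line))) next
    f <- parse_fields(line)
    if (length(f) < 2) {
      stop("malformed entry line ", delim[2] + i, ": '", line, "'")
    }
    ids <- suppressWarnings(as.integer(f[-1]))
    if (anyNA(ids)) {
      stop("entry line ", delim[2] + i,
           ": non-numeric category field (multi-word terms are not supported): '",
           line, "'")
    }
    term <- tolower(f[1])
    is_stem <- grepl("\\*$", term)
    pattern <- sub("\\*$", "", term)
    bad <- setdiff(ids, categories$id)
    if (length(bad) > 0) {
      stop("entry line ", delim[2] + i, ": undeclared category id ",
           paste(bad, collapse = ", "))
    }
    pats <- c(pats, pattern); stems <- c(stems, is_stem)
    catsets[[length(catsets) + 1L]] <- sort(unique(ids))
  }
  entries <- tibble::tibble(
    pattern = pats, is_stem = stems,
    categories = if (length(catsets)) catsets else list()
  )
  moral_lexicon(name, categories, entries)
}

#' Serialize a moral lexicon to LIWC `.dic` lines
#'
#' Inverse of [parse_liwc_dic()]: parsing the returned lines yields an
#' identical lexicon (round-trip).
#'
#' @param lexicon A `moral_lexicon`.
#' @param path Optional file path; when given, the lines are also written
#'   there in UTF-8.
#' @return The `.dic` lines, invisibly when `path` is given.
#' @export
write_liwc_dic <- function(lexicon, path = NULL) {
  stopifnot(inherits(lexicon, "moral_lexicon"))
  header <- sprintf("%02d\t%s", lexicon$categories$id, lexicon$categories$name)
  body <- character(0)
  if (nrow(lexicon$entries) > 0) {
    terms <- ifelse(lexicon$entries$is_stem,
                    paste0(lexicon$entries$pattern, "*"),
                    lexicon$entries$pattern)
    ids <- vapply(lexicon$entries$categories,
                  function(x) paste(sprintf("%02d", x), collapse = "\t"), "")
    body <- paste0(terms, "\t", ids)
  }
  lines <- c("%", header, "%", body)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = FALSE)
    return(invisible(lines))
  }
  lines
}

#' Match a token against a moral lexicon
#'
#' Returns the union of category ids from every exact entry whose pattern
#' equals the token and every stem entry whose pattern is a prefix of the
#' token (a stem matches its own pattern too). A token may map to several
#' categories and several foundations; an unmatched token yields an empty
#' set.
#'
#' @param lexicon A `moral_lexicon`.
#' @param token A single lowercase, non-empty token.
#' @return Sorted integer vector of matched category ids (possibly empty).
#' @export
match_token <- function(lexicon, token) {
  stopifnot(inherits(lexicon, "moral_lexicon"),
            is.character(token), length(token) == 1L, nzchar(token))
  e <- lexicon$entries
  if (nrow(e) == 0) return(integer(0))
  hit <- (!e$is_stem & e$pattern == token) |
    (e$is_stem & startsWith(token, e$pattern))
  sort(unique(as.integer(unlist(e$categories[hit], use.names = FALSE))))
}

# Foundations (excluding GENERAL unless include_general) that a token maps
# to, as a character vector. Vectorised over a token vector via
# token_foundation_sets().
token_foundations <- function(lexicon, token, include_general = FALSE) {
  ids <- match_token(lexicon, token)
  if (length(ids) == 0) return(character(0))
  f <- lexicon$categories$foundation[match(ids, lexicon$categories$id)]
  f <- unique(f)
  if (!include_general) f <- setdiff(f, "GENERAL")
  f[order(match(f, moral_foundations()))]
}

# One foundation set per unique token, returned as a list keyed by token.
# Used by the corpus scorer so each distinct token is matched once.
token_foundation_sets <- function(lexicon, tokens) {
  uniq <- unique(tokens)
  sets <- lapply(uniq, function(tk) token_foundations(lexicon, tk))
  names(sets) <- uniq
  sets
}

#' @export
print.moral_lexicon <- function(x, ...) {
  cat("<moral_lexicon> ", x$name, "\n", sep = "")
  cat("  categories: ", nrow(x$categories), "\n", sep = "")
  n_stem <- sum(x$entries$is_stem)
  cat("  entries: ", nrow(x$entries), " (", nrow(x$entries) - n_stem,
      " words, ", n_stem, " stems)\n", sep = "")
  invisible(x)
}

#' Summarize a lexicon's category table and entry counts
#'
#' @param lexicon A `moral_lexicon`.
#' @return A tibble with one row per category: id, name, foundation,
#'   polarity, and the number of word and stem entries assigned to it.
#' @export
lexicon_summary <- function(lexicon) {
  stopifnot(inherits(lexicon, "moral_lexicon"))
  per_cat <- function(id) {
    hit <- vapply(lexicon$entries$categories, function(s) id %in% s, NA)
    c(words = sum(hit & !lexicon$entries$is_stem),
      stems = sum(hit & lexicon$entries$is_stem))
  }
  counts <- t(vapply(lexicon$categories$id, per_cat, c(words = 0, stems = 0)))
  dplyr::bind_cols(lexicon$categories,
                   tibble::as_tibble(as.data.frame(counts)))
}
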