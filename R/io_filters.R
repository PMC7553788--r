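#' Corpus input, output and relevance/quality filters
#'
#' A *corpus* is a tibble of timestamped documents with one row per document
#' and columns `id`, `timestamp` (Date), `source` (one of `"news"`,
#' `"reddit_submission"`, `"reddit_comment"`, `"youtube"`), `title`, `body`,
#' `score` (platform vote score, meaningful for submissions), `comment_count`
#' (the per-document comment volume used to weight discussion-platform topic
#' strength) and `author_id`. Corpora are interchanged as JSON-Lines, one
#' record per line.
#'
#' @name corpus
NULL

corpus_cols <- c("id", "timestamp", "source", "title", "body",
                 "score", "comment_count", "author_id")

corpus_sources <- c("news", "reddit_submission", "reddit_comment", "youtube")

# Coerce a list-of-records into a corpus tibble with canonical column types.
as_corpus <- function(records) {
  if (length(records) == 0) {
    return(tibble::tibble(
      id = character(), timestamp = as.Date(character()), source = character(),
      title = character(), body = character(), score = integer(),
      comment_count = integer(), author_id = character()
    ))
  }
  grab <- function(field, default) {
    purrr::map(records, ~ .x[[field]] %||% default)
  }
  tibble::tibble(
    id = as.character(unlist(grab("id", NA_character_))),
    timestamp = as.Date(unlist(grab("timestamp", NA_character_))),
    source = as.character(unlist(grab("source", NA_character_))),
    title = as.character(unlist(grab("title", ""))),
    body = as.character(unlist(grab("body", ""))),
    score = as.integer(unlist(grab("score", NA_integer_))),
    comment_count = as.integer(unlist(grab("comment_count", 0L))),
    author_id = as.character(unlist(grab("author_id", NA_character_)))
  )
}

#' Read a JSON-Lines corpus
#'
#' Parses one JSON object per line into a corpus tibble. Malformed lines
#' (unparsable JSON, or records missing `id` or `timestamp`) are skipped and
#' counted; the skip count is attached as attribute `"skipped"` and reported.
#' More than 50% malformed lines is treated as a wrong-format error.
#'
#' @param path Path to a JSON-Lines file.
#' @param source_kind Optional source tag (`"news"`, `"reddit_submission"`,
#'   `"reddit_comment"`, `"youtube"`) assigned to records that carry none.
#' @return A corpus tibble (see [corpus]) with attribute `skipped`.
#' @export
read_corpus <- function(path, source_kind = NULL) {
  if (!file.exists(path)) abort(paste("corpus file not found:", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste("empty corpus file:", path))
    out <- as_corpus(list())
    attr(out, "skipped") <- 0L
    return(out)
  }
  parsed <- purrr::map(lines, function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) return(NULL)
    if (is.null(rec$id) || is.null(rec$timestamp)) return(NULL)
    if (!is.null(rec$timestamp)) {
      ts <- tryCatch(as.Date(rec$timestamp), error = function(e) NA)
      if (is.na(ts)) return(NULL)
    }
    rec
  })
  bad <- purrr::map_lgl(parsed, is.null)
  if (mean(bad) > 0.5) {
    abort(paste0("more than 50% of lines in ", path,
                 " are malformed (", sum(bad), "/", length(bad),
                 "); is this really a JSON-Lines corpus?"))
  }
  out <- as_corpus(parsed[!bad])
  if (!is.null(source_kind)) {
    source_kind <- match.arg(source_kind, corpus_sources)
    out$source[is.na(out$source)] <- source_kind
  }
  if (any(bad)) inform(paste("read_corpus: skipped", sum(bad), "malformed record(s)"))
  attr(out, "skipped") <- sum(bad)
  out
}

#' Write a corpus as JSON-Lines
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- as.list(corpus[i, corpus_cols[corpus_cols %in% names(corpus)]])
    rec$timestamp <- format(rec$timestamp)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Pandemic-relevance keyword lists
#'
#' The keyword lists used to select relevant documents: one for news articles
#' and one for video metadata, matched case-insensitively as whole word
#' tokens (hyphenated terms such as `"covid-19"` count as one token).
#'
#' @return Character vector of lowercase keywords.
#' @export
news_keywords <- function() {
  c("coronavirus", "covid19", "covid-19", "ncov-19", "sars-cov-2")
}

#' @rdname news_keywords
#' @export
youtube_keywords <- function() {
  c("coronavirus", "virus", "covid", "covid19", "sars", "sars-cov-2", "sarscov2")
}

#' Keep documents citing at least one keyword
#'
#' Retains exactly the documents in which at least one keyword occurs as a
#' whole token (case-insensitive) in one of the searched fields. Document
#' order is preserved and documents are never modified, so the operation is
#' idempotent.
#'
#' @param corpus A corpus tibble.
#' @param keywords Character vector of lowercase keywords (non-empty).
#' @param fields Fields searched, a subset of `c("title", "body")`.
#' @return The filtered corpus tibble.
#' @export
#' @examples
#' corp <- tibble::tibble(
#'   id = c("a", "b"), timestamp = as.Date("2020-03-01"), source = "news",
#'   title = c("covid-19 surges", "election news"), body = "",
#'   score = 0L, comment_count = 0L, author_id = "x"
#' )
#' filter_by_keywords(corp, news_keywords())
filter_by_keywords <- function(corpus, keywords,
                               fields = c("title", "body")) {
  if (length(keywords) == 0) abort("keyword list must be non-empty")
  fields <- match.arg(fields, c("title", "body"), several.ok = TRUE)
  keywords <- tolower(keywords)
  if (nrow(corpus) == 0) return(corpus)
  text <- do.call(paste, c(unname(corpus[fields]), sep = " "))
  hit <- purrr::map_lgl(tokenize(text), ~ any(.x %in% keywords))
  corpus[hit, , drop = FALSE]
}

#' Quality-filter a discussion-platform corpus
#'
#' Applies the submission and comment cleaning rules: submissions with vote
#' score of 1 or less are dropped (spam control); comments whose body is
#' shorter than 10 characters (Unicode code points, after trimming
#' leading/trailing whitespace) are dropped; and any comment body occurring
#' more than 3 times across the comment corpus has *all* of its occurrences
#' dropped, since such mass-duplicated text is bot or moderator boilerplate.
#' Submission rules never touch comments and vice versa.
#'
#' @param submissions Corpus tibble of submissions.
#' @param comments Corpus tibble of comments.
#' @param min_score Submissions must have `score` strictly greater than this
#'   (default 1).
#' @param min_chars Minimum comment body length in characters (default 10).
#' @param max_duplicates Maximum allowed occurrences of an identical comment
#'   body (default 3); bodies exceeding it are removed wholesale.
#' @return A list with filtered `submissions` and `comments` tibbles and a
#'   `removed` list of counts
#'   (`submissions_low_score`, `comments_short`, `comments_duplicate`).
#' @export
clean_reddit <- function(submissions, comments,
                         min_score = 1L, min_chars = 10L, max_duplicates = 3L) {
  keep_sub <- !is.na(submissions$score) & submissions$score > min_score
  body <- trimws(comments$body)
  long_enough <- nchar(body, type = "chars") >= min_chars
  n_short <- sum(!long_enough)
  # duplicate counts are taken over the whole comment corpus, before the
  # length cut, so boilerplate short variants still count toward duplication
  dup_tab <- table(body)
  is_spam <- as.vector(dup_tab[body]) > max_duplicates
  keep_com <- long_enough & !is_spam
  list(
    submissions = submissions[keep_sub, , drop = FALSE],
    comments = comments[keep_com, , drop = FALSE],
    removed = list(
      submissions_low_score = sum(!keep_sub),
      comments_short = n_short,
      comments_duplicate = sum(is_spam & long_enough)
    )
  )
}
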