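#' Self-report geolocation and location-citation shares
#'
#' Discussion platforms rarely expose user locations, but users volunteer
#' them in phrases like "I live in Toronto". This module extracts such
#' candidate phrases with trigger-pattern matching, resolves them against a
#' small bundled gazetteer (country names, demonyms and major cities of the
#' study countries plus China, each mapped to an ISO-3166 alpha-2 code), and
#' assigns a user a country only when every resolved self-report agrees —
#' inconsistent self-reporters are left unassigned, trading recall for
#' precision. The same gazetteer supports counting location *citations* in
#' document text, used to track how media attention shifts from foreign to
#' domestic locations around a pivotal date.
#'
#' @name geolocation
NULL

#' Load a gazetteer
#'
#' Reads a two-column CSV (`surface_form,country`), lowercases surface
#' forms, and drops any surface form mapped to more than one country
#' (precision over recall). The default is the bundled gazetteer covering
#' Italy, the United Kingdom, the United States, Canada and China.
#'
#' @param path CSV path; default the bundled file.
#' @return A tibble `surface_form`, `country` of class `gazetteer`.
#' @export
load_gazetteer <- function(path = system.file("extdata", "gazetteer.csv",
                                              package = "infodemics")) {
  gaz <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("surface_form", "country") %in% names(gaz))) {
    abort("gazetteer CSV must have columns surface_form,country")
  }
  gaz$surface_form <- tolower(trimws(gaz$surface_form))
  gaz$country <- toupper(trimws(gaz$country))
  if (any(nchar(gaz$country) != 2)) abort("country codes must be ISO-3166 alpha-2")
  # ambiguous surface forms (same form, several countries) are dropped
  amb <- gaz |>
    dplyr::distinct(.data$surface_form, .data$country) |>
    dplyr::count(.data$surface_form) |>
    dplyr::filter(.data$n > 1)
  gaz <- gaz |>
    dplyr::filter(!.data$surface_form %in% amb$surface_form) |>
    dplyr::distinct(.data$surface_form, .data$country)
  class(gaz) <- c("gazetteer", class(gaz))
  gaz
}

self_report_triggers <- c("i am from", "i'm from", "i live in")

#' Extract location self-report candidates
#'
#' Scans document text (title and body) case-insensitively for the trigger
#' phrases "i am from", "i'm from" and "i live in" and captures the
#' following span, truncated at the first punctuation mark or after 4
#' tokens, whichever comes first.
#'
#' @param corpus Corpus tibble with `author_id`.
#' @return Tibble `author_id`, `doc_id`, `phrase` (lowercase), one row per
#'   match.
#' @export
extract_self_reports <- function(corpus) {
  if (nrow(corpus) == 0) {
    return(tibble::tibble(author_id = character(), doc_id = character(),
                          phrase = character()))
  }
  text <- tolower(paste(corpus$title, corpus$body))
  pattern <- paste0("(?:", paste(gsub("'", "'", self_report_triggers, fixed = TRUE),
                                 collapse = "|"),
                    ")\\s+([^.,;:!?\\n]+)")
  purrr::map_dfr(seq_along(text), function(i) {
    m <- regmatches(text[i], gregexpr(pattern, text[i], perl = TRUE))[[1]]
    if (length(m) == 0) return(NULL)
    span <- sub(pattern, "\\1", m, perl = TRUE)
    phrase <- vapply(span, function(s) {
      tk <- strsplit(trimws(s), "\\s+")[[1]]
      paste(head(tk, 4), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    tibble::tibble(author_id = corpus$author_id[i], doc_id = corpus$id[i],
                   phrase = phrase)
  })
}

# resolve one phrase: try the full span, then shorter leading spans
resolve_phrase <- function(phrase, lookup) {
  tk <- strsplit(phrase, "\\s+")[[1]]
  for (k in rev(seq_along(tk))) {
    cand <- paste(head(tk, k), collapse = " ")
    hit <- lookup[[cand]]
    if (!is.null(hit)) return(hit)
  }
  NA_character_
}

#' Resolve self-report candidates to user countries
#'
#' Maps each candidate phrase through the gazetteer (longest leading span
#' first, so "toronto so" still resolves via "toronto"). A user whose
#' resolved candidates all agree is assigned that country; disagreeing
#' candidates leave the user unassigned; unresolvable candidates are
#' ignored.
#'
#' @param candidates Tibble from [extract_self_reports()].
#' @param gazetteer A [load_gazetteer()] tibble.
#' @return Tibble `author_id`, `country` (`NA` when unassigned),
#'   `evidence` (list column of matched phrases).
#' @export
resolve_user_country <- function(candidates, gazetteer = load_gazetteer()) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(author_id = character(), country = character(),
                          evidence = list()))
  }
  lookup <- as.list(stats::setNames(gazetteer$country, gazetteer$surface_form))
  candidates$country <- vapply(candidates$phrase, resolve_phrase,
                               character(1), lookup = lookup,
                               USE.NAMES = FALSE)
  candidates |>
    dplyr::group_by(author_id = .data$author_id) |>
    dplyr::summarise(
      country = {
        cc <- unique(stats::na.omit(.data$country))
        if (length(cc) == 1) cc else NA_character_
      },
      evidence = list(.data$phrase[!is.na(.data$country)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(evidence = ifelse(is.na(.data$country),
                                    list(character(0)), .data$evidence))
}

# count gazetteer mentions attributable to each country in a text vector
count_mentions <- function(text, gazetteer, countries) {
  gaz <- gazetteer[gazetteer$country %in% countries, ]
  text <- tolower(text)
  counts <- stats::setNames(numeric(length(countries)), countries)
  for (i in seq_len(nrow(gaz))) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              gaz$surface_form[i]), "\\b")
    hits <- vapply(gregexpr(pat, text, perl = TRUE),
                   function(m) sum(m > 0), numeric(1))
    counts[gaz$country[i]] <- counts[gaz$country[i]] + sum(hits)
  }
  counts
}

#' Home-versus-foreign citation shares around a split date
#'
#' Counts gazetteer location mentions attributable to a home country and a
#' foreign country in document bodies, partitions the documents at
#' `split_date` (documents on or after the date fall in the "after"
#' partition), and reports the home share `home / (home + foreign)` in each
#' partition. A partition with no mentions yields an `NA` share, flagged
#' `defined = FALSE`.
#'
#' @param corpus Corpus tibble.
#' @param home_country,foreign_country ISO-3166 alpha-2 codes.
#' @param split_date `Date` partition point (e.g. the country's first
#'   epidemic death).
#' @param gazetteer A [load_gazetteer()] tibble.
#' @return Tibble `period` (`"before"`/`"after"`), `home_mentions`,
#'   `foreign_mentions`, `home_share`, `defined`.
#' @export
citation_shares <- function(corpus, home_country, foreign_country, split_date,
                            gazetteer = load_gazetteer()) {
  split_date <- as.Date(split_date)
  if (nrow(corpus) > 0 &&
      (split_date <= min(corpus$timestamp) || split_date > max(corpus$timestamp))) {
    warn("split date lies at or outside the corpus window; one partition is empty")
  }
  countries <- c(home_country, foreign_country)
  before <- corpus$timestamp < split_date
  share_of <- function(docs) {
    if (nrow(docs) == 0) return(c(NA_real_, 0, 0))
    cnt <- count_mentions(paste(docs$title, docs$body), gazetteer, countries)
    tot <- sum(cnt)
    c(if (tot > 0) cnt[[home_country]] / tot else NA_real_,
      cnt[[home_country]], cnt[[foreign_country]])
  }
  b <- share_of(corpus[before, , drop = FALSE])
  a <- share_of(corpus[!before, , drop = FALSE])
  tibble::tibble(
    period = c("before", "after"),
    home_mentions = c(b[2], a[2]),
    foreign_mentions = c(b[3], a[3]),
    home_share = c(b[1], a[1]),
    defined = !is.na(c(b[1], a[1]))
  )
}
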