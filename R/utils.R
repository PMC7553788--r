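#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats sd qt pt pf pnorm cor rnorm runif rpois rnbinom rbinom
#' @importFrom utils head tail
NULL

# Tokenizer used consistently by filters, vocabulary building and the
# gazetteer matcher: lowercase word tokens, splitting on non-alphanumerics
# except internal hyphens, so "covid-19" and "sars-cov-2" stay single tokens.
tokenize <- function(text) {
  text <- tolower(text)
  m <- gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", text)
  regmatches(text, m)
}

# sample-sd z-score of a numeric vector; errors on zero variance
zscore_vec <- function(x) {
  if (length(x) < 2) abort("zscore requires length >= 2")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("zscore undefined: series has zero variance")
  (x - mean(x)) / s
}

#' Standardize a signal to zero mean and unit variance
#'
#' Z-scores a numeric vector, or the `value` column of a time-series tibble
#' (columns `date`, `value`, optionally `country` and `kind`), using the
#' unbiased (n - 1) standard deviation. Standardized signals make regression
#' coefficients comparable across countries and volume scales.
#'
#' @param x Numeric vector, or data frame with a `value` column.
#' @return Same shape as the input with values standardized.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("value" %in% names(x))
    x$value <- zscore_vec(x$value)
    return(tibble::as_tibble(x))
  }
  zscore_vec(x)
}

# Pull the value column out of a series given as a vector or tibble.
series_values <- function(x, arg = "series") {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) abort(paste0("`", arg, "` must have a `value` column"))
    return(x$value)
  }
  if (!is.numeric(x)) abort(paste0("`", arg, "` must be numeric or a data frame"))
  as.numeric(x)
}

#' Read a (date, country, kind, value) time-series CSV
#'
#' @param path Path to a CSV with header `date,country,kind,value`.
#' @return A tibble with `date` parsed as `Date` and `value` numeric.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "country", "kind", "value")
  if (!all(need %in% names(df))) {
    abort(paste("time-series CSV must have columns", paste(need, collapse = ", ")))
  }
  df$date <- as.Date(df$date)
  df$value <- as.numeric(df$value)
  tibble::as_tibble(df)
}

#' Write a time-series tibble as CSV
#' @param series Tibble with columns `date`, `country`, `kind`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
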