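# build a corpus tibble tersely; unspecified fields get harmless defaults
make_corpus <- function(..., n = NULL) {
  given <- list(...)
  n <- n %||% max(1L, lengths(given))
  defaults <- list(
    id = sprintf("d%03d", seq_len(n)),
    timestamp = rep(as.Date("2020-03-01"), n),
    source = rep("news", n),
    title = rep("", n),
    body = rep("", n),
    score = rep(0L, n),
    comment_count = rep(0L, n),
    author_id = sprintf("u%03d", seq_len(n))
  )
  for (nm in names(given)) defaults[[nm]] <- rep(given[[nm]], length.out = n)
  tibble::as_tibble(defaults)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent double-loop oracle for the exponential-memory covariate
mem_oracle <- function(x, tau, include_current_day = FALSE) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    past <- if (include_current_day) seq_len(t) else seq_len(t - 1L)
    if (length(past) == 0) return(0)
    sum(x[past] * exp(-(t - past) / tau))
  }, numeric(1))
}

# independent normal-equations OLS oracle
ols_oracle <- function(y, X) solve(crossprod(X), crossprod(X, y))

# tiny gazetteer written to a temp CSV
write_temp_gazetteer <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
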