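#' Topic extraction and dynamics
#'
#' Topics are extracted from a reference corpus by nonnegative matrix
#' factorization of its TF-IDF matrix,
#' \deqn{\min_{W, H \ge 0} \; \lVert X - W H \rVert_F^2,}
#' with \eqn{X \in \mathbb{R}^{|D| \times |V|}} the TF-IDF matrix, \eqn{H}
#' a \eqn{K \times |V|} topic-term basis and \eqn{W} the document-topic
#' weights, minimized by alternating projected gradient descent. The fitted
#' basis \eqn{H} is then held fixed to project other corpora onto the same
#' topics, which makes interest directly comparable across sources. Topic
#' dynamics are summarized by the per-day strength
#' \eqn{s_k(t) = \sum_{i \in D^{(t)}} w_i W_{ik}} (with \eqn{w_i = 1} for
#' news and \eqn{w_i = c_i}, the comment count, for discussion platforms),
#' the relevance \eqn{R_k = \sum_t s_k(t)}, the half-relevance time
#' \eqn{t_{1/2}} at which cumulative strength first reaches \eqn{R_k/2},
#' and per-source percentage interest shares.
#'
#' @name topics
NULL

count_tokens <- function(tokens) {
  # tokens: list of character vectors; returns list of named counts
  lapply(tokens, function(tk) {
    if (length(tk) == 0) return(integer(0))
    table(tk)
  })
}

doc_bigrams <- function(tokens) {
  lapply(tokens, function(tk) {
    if (length(tk) < 2) return(character(0))
    paste(tk[-length(tk)], tk[-1], sep = "_")
  })
}

#' Build a vocabulary of unigrams and collocation bigrams
#'
#' Tokenizes the corpus (lowercase words, internal hyphens kept), promotes
#' frequent, strongly associated bigrams to single terms (joint corpus count
#' at least `bigram_min_count` and pointwise mutual information above
#' `pmi_threshold`), then discards terms whose *document* frequency is below
#' `min_df`. Term order is lexicographic, so the vocabulary is deterministic.
#'
#' @param corpus A corpus tibble (see [corpus]).
#' @param min_df Minimum document frequency for a term to be retained
#'   (default 10).
#' @param bigram_min_count Minimum corpus-wide occurrence count for a bigram
#'   to be considered (default 10).
#' @param pmi_threshold Minimum pointwise mutual information (natural log
#'   scale) for a bigram to be promoted (default 2).
#' @param fields Text fields used, subset of `c("title", "body")`.
#' @return An object of class `vocabulary`: `terms` (ordered character
#'   vector), `doc_freq` (named integer vector), `n_docs`.
#' @export
build_vocabulary <- function(corpus, min_df = 10L, bigram_min_count = 10L,
                             pmi_threshold = 2, fields = c("title", "body")) {
  if (nrow(corpus) == 0) abort("cannot build a vocabulary from an empty corpus")
  fields <- intersect(fields, names(corpus))
  text <- do.call(paste, c(unname(corpus[fields]), sep = " "))
  tokens <- tokenize(text)

  uni_tot <- table(unlist(tokens))
  n_tok <- sum(uni_tot)
  bigrams <- doc_bigrams(tokens)
  bi_tot <- table(unlist(bigrams))
  bi_tot <- bi_tot[bi_tot >= bigram_min_count]
  promoted <- character(0)
  if (length(bi_tot) > 0) {
    parts <- strsplit(names(bi_tot), "_", fixed = TRUE)
    pmi <- vapply(seq_along(bi_tot), function(i) {
      w <- parts[[i]]
      if (length(w) != 2) return(-Inf) # parts containing "_" from hyphens etc.
      log(as.numeric(bi_tot[i]) * n_tok /
            (as.numeric(uni_tot[w[1]]) * as.numeric(uni_tot[w[2]])))
    }, numeric(1))
    promoted <- names(bi_tot)[is.finite(pmi) & pmi >= pmi_threshold]
  }

  uni_df <- table(unlist(lapply(tokens, unique)))
  df_all <- as.integer(uni_df); names(df_all) <- names(uni_df)
  if (length(promoted) > 0) {
    bi_df <- table(unlist(lapply(bigrams, function(b) unique(b[b %in% promoted]))))
    add <- as.integer(bi_df); names(add) <- names(bi_df)
    df_all <- c(df_all, add)
  }
  keep <- df_all >= min_df
  terms <- sort(names(df_all)[keep])
  if (length(terms) == 0) abort("vocabulary is empty after the min_df cut")
  structure(
    list(terms = terms, doc_freq = df_all[terms], n_docs = length(tokens),
         min_df = min_df, bigrams = intersect(promoted, terms)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("Vocabulary:", length(x$terms), "terms (",
      length(x$bigrams), "bigrams ) over", x$n_docs, "documents\n")
  invisible(x)
}

#' TF-IDF matrix of a corpus over a fixed vocabulary
#'
#' Raw term counts are weighted by smoothed inverse document frequency
#' `idf = ln((1 + |D|)/(1 + df)) + 1` — with `|D|` and `df` taken from the
#' vocabulary's reference corpus, so projections of new corpora live in the
#' same feature space — and each document row is L2-normalized (all-zero
#' rows stay zero).
#'
#' @param corpus A corpus tibble.
#' @param vocab A `vocabulary` from [build_vocabulary()].
#' @param fields Text fields used.
#' @return A dense numeric matrix, documents in rows (named by `id`), terms
#'   in columns.
#' @export
tfidf_matrix <- function(corpus, vocab, fields = c("title", "body")) {
  fields <- intersect(fields, names(corpus))
  text <- do.call(paste, c(unname(corpus[fields]), sep = " "))
  tokens <- tokenize(text)
  terms <- vocab$terms
  X <- matrix(0, nrow = length(tokens), ncol = length(terms),
              dimnames = list(corpus$id, terms))
  has_bigrams <- length(vocab$bigrams) > 0
  for (i in seq_along(tokens)) {
    tk <- tokens[[i]]
    if (has_bigrams && length(tk) > 1) {
      bg <- paste(tk[-length(tk)], tk[-1], sep = "_")
      tk <- c(tk, bg[bg %in% vocab$bigrams])
    }
    tk <- tk[tk %in% terms]
    if (length(tk) == 0) next
    cnt <- table(tk)
    X[i, names(cnt)] <- as.numeric(cnt)
  }
  idf <- log((1 + vocab$n_docs) / (1 + as.numeric(vocab$doc_freq))) + 1
  X <- sweep(X, 2, idf, `*`)
  norms <- sqrt(rowSums(X^2))
  nz <- norms > 0
  X[nz, ] <- X[nz, , drop = FALSE] / norms[nz]
  X
}

# one block of projected-gradient descent on min_{W>=0} ||X - W H||_F^2,
# H fixed; step 1/L with L = ||H H'||_2 guarantees monotone decrease
pgd_update_W <- function(X, W, H, inner, l1 = 0) {
  HHt <- H %*% t(H)
  L <- max(eigen(HHt, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(W)
  XHt <- X %*% t(H)
  for (j in seq_len(inner)) {
    G <- W %*% HHt - XHt
    W <- pmax(W - (G + l1) / L, 0)
  }
  W
}

nmf_objective <- function(X, W, H) sum((X - W %*% H)^2)

#' Fit a topic model by projected-gradient NMF
#'
#' Alternating projected gradient descent on
#' \eqn{\lVert X - WH \rVert_F^2} with elementwise nonnegativity
#' projection. Each block update takes gradient steps of size `1/L` (L the
#' spectral norm of the block's quadratic term), so the objective trace is
#' non-increasing by construction. Initialization is uniform random scaled
#' to the data magnitude and fully determined by `seed`. An optional L1
#' penalty on `W` (`sparseness`) promotes sparse document loadings.
#'
#' @param X Nonnegative document-term matrix (typically from
#'   [tfidf_matrix()]).
#' @param K Number of topics; must satisfy `K < min(dim(X))`. The reference
#'   analysis uses `K = 64` on a full-scale corpus.
#' @param seed Integer seed for the random initialization.
#' @param tol Stop when the relative objective decrease falls below this
#'   (default `1e-5`).
#' @param max_iter Maximum outer iterations (default 200).
#' @param inner Gradient steps per block update (default 4).
#' @param sparseness Optional nonnegative L1 weight on `W` (default 0, off).
#' @return An object of class `topic_model`: `H` (K x |V| basis, rows named
#'   `topic_k`), `W` (|D| x K weights), `objective_trace`, `K`, `seed`,
#'   `iterations`, `converged`.
#' @export
nmf_fit <- function(X, K, seed = 1L, tol = 1e-5, max_iter = 200L,
                    inner = 4L, sparseness = 0) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("X contains non-finite entries")
  if (any(X < 0)) abort("X must be nonnegative")
  if (K >= min(dim(X))) abort("K must be smaller than both dimensions of X")
  set.seed(seed)
  scale0 <- sqrt(mean(X) / K)
  W <- matrix(runif(nrow(X) * K), nrow(X), K) * scale0
  H <- matrix(runif(K * ncol(X)), K, ncol(X)) * scale0
  trace <- nmf_objective(X, W, H)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    W <- pgd_update_W(X, W, H, inner, l1 = sparseness)
    H <- t(pgd_update_W(t(X), t(H), t(W), inner))
    obj <- nmf_objective(X, W, H)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (prev > 0 && (prev - obj) / prev < tol) { converged <- TRUE; break }
  }
  rownames(H) <- paste0("topic_", seq_len(K))
  colnames(H) <- colnames(X)
  colnames(W) <- rownames(H)
  rownames(W) <- rownames(X)
  structure(
    list(H = H, W = W, K = K, seed = seed, objective_trace = trace,
         iterations = it, converged = converged),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  tr <- x$objective_trace
  cat("Topic model: K =", x$K, ", |V| =", ncol(x$H),
      ", objective", signif(tr[length(tr)], 5),
      "after", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Project a corpus onto a fixed topic basis
#'
#' Solves the nonnegative least-squares subproblem
#' \eqn{\min_{W \ge 0} \lVert X_{new} - W H \rVert_F^2} with the basis `H`
#' held fixed, using the same projected-gradient solver and stopping rule as
#' [nmf_fit()]. This expresses a second corpus in the topics of the
#' reference corpus.
#'
#' @param X_new Nonnegative matrix with the same column dimension as `H`.
#' @param model A `topic_model` (or a bare `H` matrix).
#' @inheritParams nmf_fit
#' @return The nonnegative weight matrix `W_new` (`nrow(X_new)` x K).
#' @export
nmf_transform <- function(X_new, model, seed = 1L, tol = 1e-5,
                          max_iter = 200L, inner = 4L) {
  H <- if (inherits(model, "topic_model")) model$H else as.matrix(model)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(H)) {
    abort(paste0("column mismatch: X_new has ", ncol(X_new),
                 " terms, basis has ", ncol(H)))
  }
  set.seed(seed)
  K <- nrow(H)
  W <- matrix(runif(nrow(X_new) * K), nrow(X_new), K) * sqrt(mean(X_new) / K)
  obj_prev <- nmf_objective(X_new, W, H)
  for (it in seq_len(max_iter)) {
    W <- pgd_update_W(X_new, W, H, inner)
    obj <- nmf_objective(X_new, W, H)
    if (obj_prev > 0 && (obj_prev - obj) / obj_prev < tol) break
    obj_prev <- obj
  }
  colnames(W) <- rownames(H)
  rownames(W) <- rownames(X_new)
  W
}

#' Top terms of each topic
#' @param model A `topic_model`.
#' @param n Number of terms per topic.
#' @return Tibble `topic`, `term`, `weight`, `rank`.
#' @export
top_terms <- function(model, n = 10L) {
  H <- model$H
  purrr::map_dfr(seq_len(nrow(H)), function(k) {
    ord <- order(H[k, ], decreasing = TRUE)[seq_len(min(n, ncol(H)))]
    tibble::tibble(topic = rownames(H)[k], term = colnames(H)[ord],
                   weight = H[k, ord], rank = seq_along(ord))
  })
}

#' Daily topic strength series
#'
#' Bins per-document topic weights into daily strengths
#' \eqn{s_k(t) = \sum_{i \in D^{(t)}} w_i W_{ik}}. Weights default to 1
#' (news corpora); pass the per-document comment counts for discussion
#' corpora. Days inside the window with no documents get 0.
#'
#' @param W Document-topic weight matrix (documents in rows).
#' @param timestamps `Date` vector, one per document row.
#' @param weights Optional nonnegative per-document weights (default all 1).
#' @param window Optional `Date` length-2 analysis window
#'   \eqn{[t_0, t_f]}; defaults to the timestamp range.
#' @return Tibble of class `topic_strengths`: `date`, `topic`, `strength`,
#'   one row per day x topic.
#' @export
topic_strength_series <- function(W, timestamps, weights = NULL, window = NULL) {
  W <- as.matrix(W)
  if (length(timestamps) != nrow(W)) abort("one timestamp per document row required")
  if (is.null(weights)) weights <- rep(1, nrow(W))
  if (any(weights < 0)) abort("document weights must be nonnegative")
  if (is.null(window)) window <- range(timestamps)
  days <- seq(window[1], window[2], by = "day")
  topics <- colnames(W) %||% paste0("topic_", seq_len(ncol(W)))
  S <- matrix(0, length(days), ncol(W), dimnames = list(format(days), topics))
  idx <- match(timestamps, days)
  if (anyNA(idx)) abort("timestamps outside the analysis window")
  WV <- W * weights
  for (k in seq_len(ncol(W))) {
    agg <- rowsum(WV[, k], idx)
    S[as.integer(rownames(agg)), k] <- agg[, 1]
  }
  out <- tibble::tibble(
    date = rep(days, times = ncol(W)),
    topic = rep(topics, each = length(days)),
    strength = as.vector(S)
  )
  class(out) <- c("topic_strengths", class(out))
  out
}

#' Topic relevance: time-integrated strength
#'
#' @param strengths A `topic_strengths` tibble.
#' @return Tibble `topic`, `relevance` (\eqn{R_k = \sum_t s_k(t)}), in the
#'   topic order of the input.
#' @export
topic_relevance <- function(strengths) {
  strengths |>
    dplyr::group_by(topic = factor(.data$topic, levels = unique(.data$topic))) |>
    dplyr::summarise(relevance = sum(.data$strength), .groups = "drop") |>
    dplyr::mutate(topic = as.character(.data$topic))
}

#' Half-relevance time of each topic
#'
#' The earliest day at which a topic's cumulative strength reaches half of
#' its total relevance. Topics with zero relevance get `NA` and are flagged.
#'
#' @param strengths A `topic_strengths` tibble.
#' @return Tibble `topic`, `t_half` (`Date`), `relevance`, `defined`.
#' @export
topic_half_time <- function(strengths) {
  strengths |>
    dplyr::group_by(topic = factor(.data$topic, levels = unique(.data$topic))) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      relevance = sum(.data$strength),
      t_half = if (sum(.data$strength) > 0) {
        .data$date[which(cumsum(.data$strength) >= sum(.data$strength) / 2)[1]]
      } else as.Date(NA),
      .groups = "drop"
    ) |>
    dplyr::mutate(topic = as.character(.data$topic),
                  defined = !is.na(.data$t_half)) |>
    dplyr::select("topic", "t_half", "relevance", "defined")
}

#' Interest-share difference between two sources
#'
#' Converts each source's per-topic relevance into percentage shares
#' (`100 R_k / sum(R)`) and subtracts them; the differences sum to zero by
#' construction. A positive difference means source 1 dedicates a larger
#' share of its attention to the topic than source 2.
#'
#' @param relevance1,relevance2 Numeric relevance vectors of equal length
#'   (or `topic_relevance()` tibbles), each with positive total.
#' @return Tibble `topic`, `share1`, `share2`, `diff` (percentage points).
#' @export
interest_share_diff <- function(relevance1, relevance2) {
  get_rel <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$relevance, r$topic) else r
  }
  r1 <- get_rel(relevance1); r2 <- get_rel(relevance2)
  if (length(r1) != length(r2)) abort("relevance vectors must have equal length")
  if (any(r1 < 0) || any(r2 < 0)) abort("relevance must be nonnegative")
  if (sum(r1) <= 0 || sum(r2) <= 0) abort("each source needs positive total relevance")
  share1 <- 100 * r1 / sum(r1)
  share2 <- 100 * r2 / sum(r2)
  tibble::tibble(
    topic = names(r1) %||% paste0("topic_", seq_along(r1)),
    share1 = unname(share1), share2 = unname(share2),
    diff = unname(share1 - share2)
  )
}

#' Document co-occurrence coherence of each topic
#'
#' For each topic's `top_n` highest-weight terms, sums over ordered term
#' pairs the log-ratio of the smoothed joint to marginal document
#' frequencies, `log((df(a, b) + s) / (df(b) + s))`. The ratio is at most 1,
#' so 0 is the ceiling, attained when the terms always co-occur; higher
#' means more coherent. Terms absent from the corpus count as frequency 0
#' under the smoothing.
#'
#' @param model A `topic_model` (or bare `H` matrix).
#' @param corpus Corpus tibble used for document frequencies.
#' @param top_n Number of top terms per topic (at least 2, default 10).
#' @param smooth Additive smoothing constant (default 1).
#' @param fields Text fields used.
#' @return Tibble `topic`, `coherence`.
#' @export
topic_coherence <- function(model, corpus, top_n = 10L, smooth = 1,
                            fields = c("title", "body")) {
  if (top_n < 2) abort("top_n must be at least 2")
  H <- if (inherits(model, "topic_model")) model$H else as.matrix(model)
  fields <- intersect(fields, names(corpus))
  text <- do.call(paste, c(unname(corpus[fields]), sep = " "))
  token_sets <- lapply(tokenize(text), unique)
  # bigram vocabulary terms ("social_distancing") require both words present
  present <- function(term, s) all(strsplit(term, "_", fixed = TRUE)[[1]] %in% s)
  df_of <- function(term) {
    sum(vapply(token_sets, function(s) present(term, s), logical(1)))
  }
  joint_of <- function(a, b) {
    sum(vapply(token_sets, function(s) present(a, s) && present(b, s), logical(1)))
  }
  purrr::map_dfr(seq_len(nrow(H)), function(k) {
    ord <- order(H[k, ], decreasing = TRUE)[seq_len(min(top_n, ncol(H)))]
    terms <- colnames(H)[ord]
    score <- 0
    for (a in terms) for (b in terms) {
      if (a == b) next
      score <- score + log((joint_of(a, b) + smooth) / (df_of(b) + smooth))
    }
    tibble::tibble(topic = rownames(H)[k] %||% paste0("topic_", k),
                   coherence = score)
  })
}

#' Match estimated topics to reference topics
#'
#' Finds the topic permutation maximizing the total cosine similarity
#' between rows of an estimated basis and rows of a reference basis
#' (factorizations are identifiable only up to permutation and scaling).
#' Exact search over permutations for `K <= 9`, greedy best-first
#' assignment above that.
#'
#' @param H_est,H_ref Matrices with the same number of rows (topics).
#' @return Tibble `est`, `ref` (row indices), `cosine`.
#' @export
match_topics <- function(H_est, H_ref) {
  H_est <- as.matrix(H_est); H_ref <- as.matrix(H_ref)
  K <- nrow(H_est)
  if (nrow(H_ref) != K) abort("bases must have the same number of topics")
  norm_rows <- function(M) {
    n <- sqrt(rowSums(M^2)); n[n == 0] <- 1
    M / n
  }
  C <- norm_rows(H_est) %*% t(norm_rows(H_ref)) # cosine similarity matrix
  if (K <= 9) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p) sum(C[cbind(seq_len(K), p)]), numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(K)
    Cw <- C
    for (step in seq_len(K)) {
      ij <- arrayInd(which.max(Cw), dim(Cw))
      best[ij[1]] <- ij[2]
      Cw[ij[1], ] <- -Inf
      Cw[, ij[2]] <- -Inf
    }
  }
  tibble::tibble(est = seq_len(K), ref = best,
                 cosine = C[cbind(seq_len(K), best)])
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    i <- i + 1L
    out[[i]] <- append(p, n, after = pos - 1L)
  }
  out
}
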