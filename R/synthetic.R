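#' Synthetic study-data generators
#'
#' Every input of the analysis pipeline can be generated with the
#' statistical structure the models assume, together with a machine-readable
#' truth record, so the whole pipeline is testable offline: a deterministic
#' SIR incidence curve, a news series driven by lagged incidence, an
#' attention series generated by the memory model (Model III) with known
#' coefficients, timestamped corpora with planted topic-term structure,
#' temporal bumps and per-topic comment affinity, and location self-report
#' sentences. All generators are fully determined by the seed in the
#' configuration.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 98-day analysis window
#' (matching a Feb 7 to May 15 span), an epidemic wave peaking inside the
#' window, news volume tracking incidence with a 1-day reporting lag and
#' 30% day-to-day noise, attention generated by the memory model with
#' \eqn{\alpha_1 = 1}, \eqn{\alpha_2 = -0.45} (saturation),
#' \eqn{\tau = 10} days and noise standard deviation 0.1 on the
#' standardized scale, 8 planted topics over a 400-term vocabulary at about
#' 20 documents/day, and overdispersed (negative-binomial) comment counts
#' whose mean is scaled by each topic's planted comment affinity.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_days Length of the analysis window in days.
#' @param start Window start date.
#' @param epi List: `transmission`, `recovery` (per day), `population`,
#'   `initial_infected`.
#' @param news List: `coefficient` (news per case), `lag` (days),
#'   `noise_sd` (fraction of the signal's sd).
#' @param attention List: `alpha1`, `alpha2`, `tau`, `noise_sd`
#'   (on the standardized scale).
#' @param topics List: `K_true`, `vocab_size`, `docs_per_day`,
#'   `doc_length`, `dirichlet`, `mixing`, `bump_centers`, `bump_width`,
#'   `comment_affinity` (length `K_true`), `comment_mean`, `nb_size`.
#' @param geoloc List: `n_users`, `report_rate`, `inconsistency_rate`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_days = 98L,
                       start = as.Date("2020-02-07"),
                       epi = list(),
                       news = list(),
                       attention = list(),
                       topics = list(),
                       geoloc = list()) {
  cfg <- list(
    seed = as.integer(seed), n_days = as.integer(n_days), start = as.Date(start),
    epi = utils::modifyList(list(transmission = 0.3, recovery = 0.1,
                                 population = 1e6, initial_infected = 10), epi),
    news = utils::modifyList(list(coefficient = 0.01, lag = 1L,
                                  noise_sd = 0.3), news),
    attention = utils::modifyList(list(alpha1 = 1.0, alpha2 = -0.45,
                                       tau = 10, noise_sd = 0.1), attention),
    topics = utils::modifyList(list(K_true = 8L, vocab_size = 400L,
                                    docs_per_day = 20L, doc_length = 50,
                                    dirichlet = 0.05, mixing = 0.1,
                                    bump_centers = NULL, bump_width = 6,
                                    comment_affinity = NULL,
                                    comment_mean = 10, nb_size = 5), topics),
    geoloc = utils::modifyList(list(n_users = 200L, report_rate = 0.5,
                                    inconsistency_rate = 0.1), geoloc)
  )
  if (any(unlist(cfg$epi) < 0) || cfg$epi$population <= 0) {
    abort("epidemic parameters must be nonnegative with positive population")
  }
  K <- cfg$topics$K_true
  if (is.null(cfg$topics$bump_centers)) {
    cfg$topics$bump_centers <- round(seq(10, cfg$n_days - 8, length.out = K))
  }
  if (is.null(cfg$topics$comment_affinity)) {
    cfg$topics$comment_affinity <- rep(c(2, 0.5), length.out = K)
  }
  if (any(cfg$topics$bump_centers < 1 | cfg$topics$bump_centers > cfg$n_days)) {
    abort("bump centers must lie within [1, n_days]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic SIR incidence curve
#'
#' Discrete-time SIR recurrence (Euler step of one day):
#' new cases \eqn{\beta S_t I_t / N}, recoveries \eqn{\gamma I_t}. The daily
#' new-case series is the incidence signal; it is single-peaked for standard
#' parameter choices and conserves \eqn{S + I + R}.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `date`, `country = "SYN"`, `kind = "incidence"`, `value`,
#'   with attribute `compartments` (matrix of S, I, R per day).
#' @export
gen_incidence <- function(cfg) {
  with(cfg$epi, {
    n <- cfg$n_days
    S <- I <- R <- inc <- numeric(n)
    S[1] <- population - initial_infected; I[1] <- initial_infected; R[1] <- 0
    inc[1] <- 0
    for (t in seq_len(n - 1)) {
      new_cases <- transmission * S[t] * I[t] / population
      new_rec <- recovery * I[t]
      S[t + 1] <- S[t] - new_cases
      I[t + 1] <- I[t] + new_cases - new_rec
      R[t + 1] <- R[t] + new_rec
      inc[t + 1] <- new_cases
    }
    out <- tibble::tibble(date = cfg$start + seq_len(n) - 1, country = "SYN",
                          kind = "incidence", value = inc)
    attr(out, "compartments") <- cbind(S = S, I = I, R = R)
    out
  })
}

#' News volume driven by lagged incidence
#'
#' `news_t = max(0, a * incidence_{t-lag} + eps)` with Gaussian noise whose
#' sd is `noise_sd` times the sd of the noiseless signal.
#'
#' @param incidence Incidence tibble from [gen_incidence()] (or numeric
#'   vector).
#' @param cfg A [sim_config()].
#' @return Tibble `date`, `country`, `kind = "news"`, `value`.
#' @export
gen_news <- function(incidence, cfg) {
  inc <- series_values(incidence, "incidence")
  n <- length(inc)
  lag <- cfg$news$lag
  if (lag >= n) abort("news lag must be smaller than the window length")
  signal <- cfg$news$coefficient * c(rep(0, lag), head(inc, n - lag))
  eps <- rnorm(n, 0, cfg$news$noise_sd * max(sd(signal), .Machine$double.eps))
  value <- pmax(0, signal + eps)
  tibble::tibble(date = cfg$start + seq_len(n) - 1, country = "SYN",
                 kind = "news", value = value)
}

#' Attention series generated by the memory model
#'
#' Standardizes the news series, builds the strictly-past memory covariate
#' at the configured \eqn{\tau} and standardizes it too, then draws
#' \deqn{y_t = \alpha_1\, \mathrm{news}^z_t + \alpha_2\, \mathrm{newsMEM}^z_t
#'       + \varepsilon_t, \qquad \varepsilon_t \sim N(0, \sigma^2),}
#' with the noise applied on the standardized scale so `noise_sd` reads as a
#' fraction of signal sd. The returned truth record carries the planted
#' coefficients and the exact standardized regressors, so recovery tests
#' can fit against the generating design.
#'
#' @param news News tibble from [gen_news()] (or numeric vector).
#' @param cfg A [sim_config()].
#' @return Tibble `date`, `country`, `kind = "attention"`, `value`, with
#'   attribute `truth`: list(`alpha1`, `alpha2`, `tau`, `noise_sd`,
#'   `news_z`, `news_mem_z`).
#' @export
gen_attention <- function(news, cfg) {
  x <- series_values(news, "news")
  a <- cfg$attention
  news_z <- zscore_vec(x)
  mem_z <- zscore_vec(build_memory_series(news_z, a$tau))
  y <- a$alpha1 * news_z + a$alpha2 * mem_z + rnorm(length(x), 0, a$noise_sd)
  out <- tibble::tibble(date = cfg$start + seq_along(x) - 1, country = "SYN",
                        kind = "attention", value = y)
  attr(out, "truth") <- list(alpha1 = a$alpha1, alpha2 = a$alpha2,
                             tau = a$tau, noise_sd = a$noise_sd,
                             news_z = news_z, news_mem_z = mem_z)
  out
}

#' One synthetic attention bundle
#'
#' Convenience wrapper generating incidence, news and attention on a shared
#' daily grid, returned wide (one column per signal) for direct use with
#' [fit_attention_model()], [tune_tau()] and [country_report()].
#'
#' @param cfg A [sim_config()]; its `seed` is applied before drawing.
#' @return Tibble `date`, `incidence`, `news`, `y`, with attribute `truth`
#'   from [gen_attention()].
#' @export
gen_attention_bundle <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  inc <- gen_incidence(cfg)
  news <- gen_news(inc, cfg)
  att <- gen_attention(news, cfg)
  out <- tibble::tibble(date = inc$date, incidence = inc$value,
                        news = news$value, y = att$value)
  attr(out, "truth") <- attr(att, "truth")
  out
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Corpus with planted topic structure, temporal bumps and comment affinity
#'
#' Draws `K_true` topic-term distributions from a sparse symmetric
#' Dirichlet, assigns each document a dominant topic (term distribution
#' `(1 - mixing) * topic + mixing * uniform-mixture-of-others`), draws its
#' term counts from a Poisson length model, places its timestamp around the
#' topic's temporal bump (Gaussian, clipped to the window), and gives the
#' discussion-platform copy a negative-binomial comment count whose mean is
#' `comment_mean * comment_affinity[k]`. Terms are `term0001`,
#' `term0002`, ... so corpora are text-only and lightweight.
#'
#' @param cfg A [sim_config()]; its `seed` is applied before drawing.
#' @param n_docs Number of documents (default `docs_per_day * n_days`).
#' @param with_text Generate document text? `FALSE` skips term sampling and
#'   leaves bodies empty, for dynamics studies that only need labels,
#'   timestamps and comment counts.
#' @param truth Optional truth record from a previous call; its planted
#'   topic-term distributions are reused, so fresh documents (e.g. a
#'   held-out set) come from the *same* topics.
#' @param seed Seed applied before drawing (default `cfg$seed`); give a
#'   different seed together with `truth` to draw an independent corpus
#'   from the same planted topics.
#' @return List: `news` corpus (unit-weight source), `reddit` corpus
#'   (comment-weighted copies), and `truth` — list(`topic_term` (K x V
#'   probability matrix), `labels`, `bump_centers`, `comment_affinity`,
#'   `vocab`).
#' @export
gen_topic_corpus <- function(cfg = sim_config(), n_docs = NULL,
                             with_text = TRUE, truth = NULL,
                             seed = cfg$seed) {
  tp <- cfg$topics
  K <- tp$K_true
  if (K < 2) abort("need at least 2 planted topics")
  V <- tp$vocab_size
  if (V < 10 * K) abort("vocab_size must be at least 10 * K_true to separate topics")
  set.seed(seed)
  n_docs <- n_docs %||% (tp$docs_per_day * cfg$n_days)
  vocab <- sprintf("term%04d", seq_len(V))
  if (is.null(truth)) {
    topic_term <- t(vapply(seq_len(K),
                           function(k) rdirichlet_one(rep(tp$dirichlet, V)),
                           numeric(V)))
    rownames(topic_term) <- paste0("topic_", seq_len(K))
    colnames(topic_term) <- vocab
  } else {
    topic_term <- truth$topic_term
    vocab <- truth$vocab
    stopifnot(nrow(topic_term) == K)
  }

  labels <- sample.int(K, n_docs, replace = TRUE)
  days <- pmin(pmax(round(rnorm(n_docs, tp$bump_centers[labels], tp$bump_width)),
                    1), cfg$n_days)
  dates <- cfg$start + days - 1
  lens <- rpois(n_docs, tp$doc_length)
  bodies <- rep("", n_docs)
  if (with_text) {
    others <- colMeans(topic_term) # population mixture for the minor component
    for (i in seq_len(n_docs)) {
      p <- (1 - tp$mixing) * topic_term[labels[i], ] + tp$mixing * others
      if (lens[i] > 0) {
        bodies[i] <- paste(sample(vocab, lens[i], replace = TRUE, prob = p),
                           collapse = " ")
      }
    }
  }
  comments <- rnbinom(n_docs, size = tp$nb_size,
                      mu = tp$comment_mean * tp$comment_affinity[labels])
  base <- tibble::tibble(
    id = sprintf("doc%05d", seq_len(n_docs)),
    timestamp = dates, title = "", body = bodies,
    score = 2L, author_id = sprintf("user%04d", sample.int(2000, n_docs, TRUE))
  )
  news <- dplyr::mutate(base, source = "news", comment_count = 0L,
                        id = paste0(.data$id, "_n"))
  reddit <- dplyr::mutate(base, source = "reddit_submission",
                          comment_count = as.integer(comments),
                          id = paste0(.data$id, "_r"))
  list(news = news[corpus_cols], reddit = reddit[corpus_cols],
       truth = list(topic_term = topic_term, labels = labels,
                    bump_centers = tp$bump_centers,
                    comment_affinity = tp$comment_affinity,
                    vocab = vocab, dates = dates))
}

#' Self-report sentences with known user countries
#'
#' For each reporting user, emits a sentence built from a trigger template
#' and a gazetteer place of the user's true country; a configured fraction
#' of reporting users additionally self-report a place from a *different*
#' country, making them inconsistent (and unresolvable by design).
#'
#' @param cfg A [sim_config()]; its `seed` is applied before drawing.
#' @param gazetteer A [load_gazetteer()] tibble supplying places.
#' @return List: `corpus` (comment corpus of self-report sentences) and
#'   `truth` — tibble `author_id`, `country` (`NA` for planted-inconsistent
#'   users), `reports`.
#' @export
gen_self_report_texts <- function(cfg = sim_config(),
                                  gazetteer = load_gazetteer()) {
  g <- cfg$geoloc
  set.seed(cfg$seed)
  templates <- c("I am from %s and stay safe.",
                 "I'm from %s but working remotely now.",
                 "I live in %s. The situation here is tense.")
  users <- sprintf("user%04d", seq_len(g$n_users))
  reporting <- runif(g$n_users) < g$report_rate
  inconsistent <- reporting & (runif(g$n_users) < g$inconsistency_rate)
  countries <- sample(unique(gazetteer$country), g$n_users, replace = TRUE)
  place_of <- function(cc) {
    forms <- gazetteer$surface_form[gazetteer$country == cc]
    sample(forms, 1)
  }
  rows <- list(); truth_country <- character(0); truth_user <- character(0)
  truth_reports <- integer(0)
  docn <- 0L
  for (i in seq_len(g$n_users)) {
    if (!reporting[i]) next
    cc <- countries[i]
    texts <- sprintf(sample(templates, 1), place_of(cc))
    if (inconsistent[i]) {
      other <- sample(setdiff(unique(gazetteer$country), cc), 1)
      texts <- c(texts, sprintf(sample(templates, 1), place_of(other)))
    }
    for (txt in texts) {
      docn <- docn + 1L
      rows[[docn]] <- tibble::tibble(
        id = sprintf("sr%05d", docn),
        timestamp = cfg$start + sample.int(cfg$n_days, 1) - 1,
        source = "reddit_comment", title = "", body = txt,
        score = 1L, comment_count = 0L, author_id = users[i]
      )
    }
    truth_user <- c(truth_user, users[i])
    truth_country <- c(truth_country, if (inconsistent[i]) NA_character_ else cc)
    truth_reports <- c(truth_reports, length(texts))
  }
  corpus <- if (docn > 0) dplyr::bind_rows(rows) else as_corpus(list())
  list(corpus = corpus[corpus_cols],
       truth = tibble::tibble(author_id = truth_user, country = truth_country,
                              reports = truth_reports))
}

#' Corpus with a planted shift in home-location citation rate
#'
#' Each document mentions either a home-country or a foreign-country place;
#' the probability of a home mention jumps from `rate_before` to
#' `rate_after` at `split_date`. Used to validate citation-share recovery.
#'
#' @param cfg A [sim_config()]; its `seed` is applied before drawing.
#' @param n_docs Number of documents (default 2000).
#' @param home,foreign ISO-3166 alpha-2 codes (default `"IT"`, `"CN"`).
#' @param rate_before,rate_after Planted home-mention probabilities
#'   (defaults 0.29 and 0.74).
#' @param split_frac Position of the split date within the window.
#' @param gazetteer Gazetteer supplying surface forms.
#' @return List: `corpus`, `split_date`, `rate_before`, `rate_after`.
#' @export
gen_citation_corpus <- function(cfg = sim_config(), n_docs = 2000L,
                                home = "IT", foreign = "CN",
                                rate_before = 0.29, rate_after = 0.74,
                                split_frac = 0.5,
                                gazetteer = load_gazetteer()) {
  set.seed(cfg$seed)
  days <- sample.int(cfg$n_days, n_docs, replace = TRUE)
  dates <- cfg$start + days - 1
  split_date <- cfg$start + round(split_frac * cfg$n_days)
  is_after <- dates >= split_date
  p_home <- ifelse(is_after, rate_after, rate_before)
  mention_home <- runif(n_docs) < p_home
  place_of <- function(cc, n) {
    sample(gazetteer$surface_form[gazetteer$country == cc], n, replace = TRUE)
  }
  place <- character(n_docs)
  place[mention_home] <- place_of(home, sum(mention_home))
  place[!mention_home] <- place_of(foreign, sum(!mention_home))
  corpus <- tibble::tibble(
    id = sprintf("cit%05d", seq_len(n_docs)), timestamp = dates,
    source = "news", title = "",
    body = sprintf("Outbreak update: new developments reported in %s today", place),
    score = 0L, comment_count = 0L,
    author_id = sprintf("outlet%02d", sample.int(20, n_docs, TRUE))
  )
  list(corpus = corpus, split_date = split_date,
       rate_before = rate_before, rate_after = rate_after)
}
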