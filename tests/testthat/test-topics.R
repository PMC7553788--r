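test_that("vocabulary applies the document-frequency cut deterministically", {
  corp <- make_corpus(
    body = c(rep("vaccine trial update", 10),
             rep("vaccine result soon", 10)),
    n = 20
  )
  v <- build_vocabulary(corp, min_df = 10, bigram_min_count = Inf)
  expect_true("vaccine" %in% v$terms)        # df = 20 >= 10
  expect_true("trial" %in% v$terms)          # df = 10: boundary, retained
  v9 <- build_vocabulary(
    make_corpus(body = c(rep("vaccine trial", 9), rep("vaccine", 11)), n = 20),
    min_df = 10, bigram_min_count = Inf
  )
  expect_false("trial" %in% v9$terms)        # df = 9 < 10 -> discarded
  expect_equal(v$terms, sort(v$terms))       # lexicographic, deterministic
  expect_error(
    build_vocabulary(make_corpus(body = "rare words only", n = 2),
                     min_df = 10, bigram_min_count = Inf),
    "empty"
  )
})

test_that("strong collocations are promoted to bigram terms", {
  set.seed(41)
  filler <- replicate(30, paste(sample(letters[1:6], 8, TRUE), collapse = " "))
  corp <- make_corpus(
    body = c(paste("people practice social distancing now", filler[1:15]),
             filler[16:30]),
    n = 30
  )
  v <- build_vocabulary(corp, min_df = 3, bigram_min_count = 10)
  expect_true("social_distancing" %in% v$terms)
  expect_true("social_distancing" %in% v$bigrams)
  # the pair occurs 15 times, above the count threshold, with high PMI
  expect_gte(unname(v$doc_freq["social_distancing"]), 15)
})

test_that("tfidf matrix matches a hand-computed oracle", {
  corp <- make_corpus(body = c("apple apple banana", "banana cherry", "date"),
                      n = 3)
  v <- build_vocabulary(corp, min_df = 1, bigram_min_count = Inf)
  X <- tfidf_matrix(corp, v)
  # hand computation: idf(t) = ln(4 / (1 + df)) + 1, rows L2-normalized
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  r1 <- c(apple = 2 * idf(1), banana = 1 * idf(2), cherry = 0, date = 0)
  r1 <- r1 / sqrt(sum(r1^2))
  expect_equal(X[1, sort(names(r1))], r1[sort(names(r1))], tolerance = 1e-10)
  # document with no vocabulary term -> zero row
  corp2 <- make_corpus(body = c("apple", "zzz qqq"), n = 2)
  X2 <- tfidf_matrix(corp2, build_vocabulary(corp2[1, ], min_df = 1,
                                             bigram_min_count = Inf))
  expect_equal(unname(X2[2, ]), rep(0, ncol(X2)))
  # single doc, single term, any count -> 1 after L2 normalization
  corp3 <- make_corpus(body = paste(rep("apple", 5), collapse = " "), n = 1)
  X3 <- tfidf_matrix(corp3, build_vocabulary(corp3, min_df = 1,
                                             bigram_min_count = Inf))
  expect_equal(unname(X3[1, 1]), 1)
})

test_that("projected-gradient NMF reconstructs planted factorizations", {
  set.seed(42)
  W0 <- matrix(rexp(60 * 4), 60, 4)
  H0 <- matrix(rexp(4 * 40), 4, 40)
  X <- W0 %*% H0
  m <- nmf_fit(X, 4, seed = 7, tol = 1e-9, max_iter = 500)
  relerr <- sqrt(sum((X - m$W %*% m$H)^2) / sum(X^2))
  expect_lt(relerr, 1e-2)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
  expect_true(all(m$H >= 0) && all(m$W >= 0))

  # rank-1 case: K = 1 recovers the dominant row pattern
  u <- rexp(30); vvec <- rexp(20)
  X1 <- outer(u, vvec)
  m1 <- nmf_fit(X1, 1, seed = 7, tol = 1e-10, max_iter = 500)
  expect_lt(sqrt(sum((X1 - m1$W %*% m1$H)^2) / sum(X1^2)), 1e-4)
  cosine <- sum(m1$H[1, ] * vvec) / sqrt(sum(m1$H[1, ]^2) * sum(vvec^2))
  expect_gt(cosine, 0.9999)

  # determinism given the seed
  m2 <- nmf_fit(X, 4, seed = 7, tol = 1e-9, max_iter = 500)
  expect_identical(m$H, m2$H)

  expect_error(nmf_fit(X, 60, seed = 1), "smaller")
  expect_error(nmf_fit(matrix(c(1, NA, 1, 1), 2), 1), "non-finite")
  expect_error(nmf_fit(-X, 2), "nonnegative")
})

test_that("fixed-basis projection solves the nonnegative regression", {
  set.seed(43)
  H <- matrix(rexp(3 * 25), 3, 25)
  m <- structure(list(H = H), class = "topic_model")
  X_new <- 3 * H[2, , drop = FALSE]
  W <- nmf_transform(X_new, m, tol = 1e-12, max_iter = 2000)
  expect_equal(unname(W[1, 2]), 3, tolerance = 1e-2)
  expect_lt(max(W[1, -2]), 1e-3 * max(W))
  # zero input -> zero weights
  expect_equal(unname(nmf_transform(matrix(0, 2, 25), m)),
               matrix(0, 2, 3), ignore_attr = TRUE)
  # projecting the training matrix attains (near) the training objective
  X <- matrix(rexp(40 * 25), 40, 25)
  fit <- nmf_fit(X, 3, seed = 9, tol = 1e-8, max_iter = 400)
  Wp <- nmf_transform(X, fit, seed = 9, tol = 1e-8, max_iter = 400)
  obj_train <- sum((X - fit$W %*% fit$H)^2)
  obj_proj <- sum((X - Wp %*% fit$H)^2)
  expect_lte(obj_proj, obj_train * (1 + 1e-3))
  expect_error(nmf_transform(matrix(1, 2, 7), m), "mismatch")
})

test_that("topic strengths bin weighted loadings by day", {
  W <- matrix(0, 4, 2, dimnames = list(NULL, c("topic_1", "topic_2")))
  W[1, 1] <- 1
  ts <- as.Date("2020-03-01") + c(2, 0, 1, 3)
  s <- topic_strength_series(W, ts, weights = c(5, 1, 1, 1),
                             window = as.Date(c("2020-03-01", "2020-03-04")))
  s1 <- s[s$topic == "topic_1", ]
  expect_equal(s1$strength, c(0, 0, 5, 0))
  # all-ones weights conserve column sums day by day
  set.seed(44)
  W2 <- matrix(rexp(30 * 3), 30, 3)
  ts2 <- as.Date("2020-03-01") + sample(0:9, 30, TRUE)
  s2 <- topic_strength_series(W2, ts2)
  expect_equal(sum(s2$strength), sum(W2))
  # brute-force per-day oracle, integer weights, exact equality
  wts <- sample(0:5, 30, TRUE)
  s3 <- topic_strength_series(W2, ts2, weights = wts)
  for (k in 1:3) {
    for (d in unique(ts2)) {
      expect_equal(
        s3$strength[s3$topic == paste0("topic_", k) & s3$date == d],
        sum(W2[ts2 == d, k] * wts[ts2 == d]),
        tolerance = 1e-12
      )
    }
  }
  # permutation invariance
  perm <- sample(30)
  s4 <- topic_strength_series(W2[perm, ], ts2[perm], weights = wts[perm])
  expect_equal(s3, s4)
  expect_error(topic_strength_series(W2, ts2, weights = rep(-1, 30)),
               "nonnegative")
  expect_error(topic_strength_series(W2, ts2[-1]), "one timestamp")
})

test_that("relevance and half-relevance time follow the cumulative rule", {
  days <- as.Date("2020-03-01") + 0:3
  s <- tibble::tibble(date = rep(days, 2),
                      topic = rep(c("A", "B"), each = 4),
                      strength = c(1, 1, 1, 1, 4, 0, 0, 0))
  class(s) <- c("topic_strengths", class(s))
  R <- topic_relevance(s)
  expect_equal(R$relevance, c(4, 4))
  th <- topic_half_time(s)
  expect_equal(th$t_half[th$topic == "A"], days[2]) # cumulative 2 >= 2
  expect_equal(th$t_half[th$topic == "B"], days[1]) # all mass at the origin
  # zero-relevance topic is flagged undefined
  s0 <- tibble::tibble(date = days, topic = "C", strength = rep(0, 4))
  th0 <- topic_half_time(s0)
  expect_true(is.na(th0$t_half))
  expect_false(th0$defined)
})

test_that("interest-share differences are zero-sum percentage points", {
  same <- interest_share_diff(c(1, 2, 3), c(2, 4, 6))
  expect_equal(same$diff, rep(0, 3))
  two <- interest_share_diff(c(3, 1), c(1, 1))
  expect_equal(two$diff, c(25, -25))
  set.seed(45)
  r1 <- rexp(8); r2 <- rexp(8)
  d <- interest_share_diff(r1, r2)
  expect_equal(sum(d$diff), 0, tolerance = 1e-6)
  expect_equal(sum(d$share1), 100, tolerance = 1e-6)
  expect_error(interest_share_diff(rep(0, 3), c(1, 2, 3)), "positive total")
  expect_error(interest_share_diff(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("coherence is maximal for always-co-occurring top terms", {
  # 10-document corpus: topic X terms always co-occur, topic Y terms never
  corp <- make_corpus(
    body = c(rep("alpha beta", 4), rep("gamma", 3), rep("delta", 3)),
    n = 10
  )
  H <- rbind(
    X = c(alpha = 1, beta = 0.9, gamma = 0, delta = 0),
    Y = c(alpha = 0, beta = 0, gamma = 1, delta = 0.9)
  )
  co <- topic_coherence(H, corp, top_n = 2)
  # X: joint df = marginal df = 4 -> both ordered-pair terms log(1) = 0,
  # the enumeration maximum for any df configuration
  expect_equal(co$coherence[1], 0)
  # Y: joint 0, marginals 3 -> 2 * log(1/4)
  expect_equal(co$coherence[2], 2 * log(1 / 4))
  expect_lt(co$coherence[2], co$coherence[1])
  expect_error(topic_coherence(H, corp, top_n = 1), "at least 2")
})

test_that("topic matching undoes a planted permutation", {
  set.seed(46)
  H <- matrix(rexp(6 * 30), 6, 30)
  perm <- sample(6)
  m <- match_topics(H[perm, ], H)
  expect_equal(m$ref, perm)
  expect_equal(m$cosine, rep(1, 6), tolerance = 1e-12)
})
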