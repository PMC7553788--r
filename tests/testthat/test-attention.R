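test_that("memory series matches the exponential-decay definition", {
  expect_equal(build_memory_series(rep(0, 4), tau = 3), rep(0, 4))
  expect_equal(build_memory_series(c(1, 0, 0), tau = 1),
               c(0, exp(-1), exp(-2)))
  # huge tau -> weights ~1 -> strictly-past cumulative sum
  x <- c(2, 1, 4, 3, 5)
  m <- build_memory_series(x, tau = 1e6)
  expect_equal(m, c(0, cumsum(x)[-5]), tolerance = 1e-3)
  # current-day variant adds the t' = t term with unit weight
  expect_equal(build_memory_series(x, tau = 2, include_current_day = TRUE),
               build_memory_series(x, tau = 2) + x)
  expect_error(build_memory_series(x, tau = 0), "positive")
})

test_that("memory series equals a double-loop oracle and is linear", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    tau <- runif(1, 0.5, 45)
    x <- rpois(n, 20)
    expect_equal(build_memory_series(x, tau), mem_oracle(x, tau),
                 tolerance = 1e-12)
    z <- rnorm(n)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(build_memory_series(a * x + b * z, tau),
                 a * build_memory_series(x, tau) + b * build_memory_series(z, tau),
                 tolerance = 1e-12)
  }
})

test_that("model fitting reproduces exact and noisy linear relationships", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9)
  d <- tibble::tibble(news = x, y = 2 * x)
  fit <- fit_attention_model(d, "II", standardize = FALSE,
                             standardize_response = FALSE, intercept = FALSE)
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$residuals), rep(0, 8), tolerance = 1e-12)

  set.seed(32)
  x1 <- rnorm(60); x2 <- rnorm(60)
  d2 <- tibble::tibble(news = x1, y = x1 - 0.5 * x2)
  # Model III with the second regressor supplied through the memory channel
  # is awkward here; fit the generic design through the same OLS core
  fit2 <- infodemics:::ols_fit(d2$y, cbind(news = x1, other = x2))
  expect_equal(unname(fit2$coefficients), c(1, -0.5), tolerance = 1e-8)

  # finite-sample orthogonal case still equals the normal-equations solution
  y3 <- rnorm(60)
  fit3 <- infodemics:::ols_fit(y3, cbind(x = x1))
  expect_equal(unname(fit3$coefficients),
               as.numeric(ols_oracle(y3, cbind(x1))), tolerance = 1e-10)
})

test_that("OLS equals the normal-equations oracle on random designs", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    fit <- infodemics:::ols_fit(y, X)
    beta <- as.numeric(ols_oracle(y, X))
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
    expect_equal(fit$rss, sum((y - X %*% beta)^2), tolerance = 1e-8)
  }
})

test_that("fit_attention_model agrees with lm and validates its inputs", {
  b <- gen_attention_bundle(sim_config(seed = 101))
  fit <- fit_attention_model(b, "III", tau = 10)
  ref <- lm(zscore(b$y) ~ 0 + news + news_mem,
            data = as.data.frame(fit$design) |>
              dplyr::mutate(news_mem = fit$design[, "news_mem"]))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-10)
  # adjusted R^2 identity
  expect_equal(fit$r2_adj,
               1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - 2 - 1))
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_error(fit_attention_model(b, "III"), "tau")
  expect_error(fit_attention_model(b[, c("date", "y")], "I"), "incidence")
  # collinear design is refused with the offender named
  d <- tibble::tibble(y = rnorm(20), incidence = rep(c(1, 2), 10))
  d$news <- d$incidence
  expect_error(
    infodemics:::ols_fit(d$y, cbind(a = d$incidence, b = d$news)),
    "collinear"
  )
})

test_that("adding a regressor never increases RSS but can lower adjusted R2", {
  set.seed(34)
  saw_adj_drop <- FALSE
  for (i in 1:20) {
    n <- 40
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- X[, 1] + rnorm(n)
    f1 <- infodemics:::ols_fit(y, X[, 1, drop = FALSE])
    f2 <- infodemics:::ols_fit(y, X)
    expect_lte(f2$rss, f1$rss + 1e-10)
    tss <- sum((y - mean(y))^2)
    adj <- function(f, p) 1 - (1 - (1 - f$rss / tss)) * (n - 1) / (n - p - 1)
    if (adj(f2, 2) < adj(f1, 1)) saw_adj_drop <- TRUE
  }
  expect_true(saw_adj_drop)
})

test_that("tau tuning maximizes adjusted R2 with first-minimum tie-breaking", {
  b <- gen_attention_bundle(sim_config(seed = 102))
  prof <- tune_tau(b, grid = c(5, 10, 20), standardize_response = FALSE)
  expect_equal(nrow(prof$profile), 3)
  expect_equal(prof$tau_best,
               prof$profile$tau[which.max(prof$profile$r2_adj)])
  expect_s3_class(prof$fit, "attention_fit")
  # one-element grid returns that element
  expect_equal(tune_tau(b, grid = 7)$tau_best, 7)
  expect_error(tune_tau(b, grid = c(3, 2, 1)), "increasing")
  expect_error(tune_tau(b, grid = numeric(0)), "non-empty")
})

test_that("F test follows the nested-model formula and direction", {
  stub <- function(terms, rss, n, model) {
    structure(list(design = matrix(0, 1, length(terms),
                                   dimnames = list(NULL, terms)),
                   rss = rss, n = n, model = model),
              class = "attention_fit")
  }
  # formula arithmetic: F = ((20-10)/1) / (10/50) = 50
  cmp <- f_test_nested(stub("news", 20, 52, "II"),
                       stub(c("news", "news_mem"), 10, 52, "III"))
  expect_equal(cmp$statistic, 50)
  expect_lt(cmp$p.value, 1e-6)
  expect_equal(cmp$p.value, pf(50, 1, 50, lower.tail = FALSE))
  expect_equal(cmp$winner, "III")
  # equal RSS -> F = 0, p = 1
  cmp0 <- f_test_nested(stub("news", 10, 52, "II"),
                        stub(c("news", "news_mem"), 10, 52, "III"))
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p.value, 1)
  expect_equal(cmp0$winner, "II")
  expect_error(f_test_nested(stub("a", 5, 52, "I"), stub("b", 4, 52, "II")),
               "not nested")
})

test_that("Cox statistic matches the reference implementation", {
  skip_if_not_installed("lmtest")
  set.seed(35)
  n <- 80
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n); x3 <- rnorm(n)
  y <- x1 + rnorm(n)
  mine <- cox_test_nonnested(y, cbind(x1 = x1), cbind(x2 = x2, x3 = x3))
  ref <- lmtest::coxtest(lm(y ~ 0 + x1), lm(y ~ 0 + x2 + x3))
  expect_equal(mine$statistic, unname(ref$`z value`), tolerance = 1e-6)
  expect_equal(mine$p.value, unname(ref$`Pr(>|z|)`), tolerance = 1e-6)
})

test_that("Cox test refuses nested or identical designs", {
  set.seed(36)
  x1 <- rnorm(30); x2 <- rnorm(30)
  y <- rnorm(30)
  expect_error(cox_test_nonnested(y, cbind(x1), cbind(x1)), "nested")
  expect_error(cox_test_nonnested(y, cbind(x1), cbind(x1, x2)), "nested")
})

test_that("pearson_with_p matches the closed-form correlation and t test", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(1, 2, 3))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(37)
  x <- rnorm(12); y <- rnorm(12)
  got <- pearson_with_p(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-10)
  tstat <- r_direct * sqrt(10 / (1 - r_direct^2))
  expect_equal(got$p.value, 2 * pt(-abs(tstat), 10), tolerance = 1e-10)
  expect_error(pearson_with_p(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "variance")
})

test_that("country_report assembles coherent tables from a bundle", {
  b <- gen_attention_bundle(sim_config(seed = 103))
  rep <- country_report(b, "SYN", tau_grid = seq(4, 20, by = 2))
  expect_equal(rep$model_r2$model, c("I", "II", "III"))
  expect_equal(nrow(rep$correlations), 3)
  expect_true(all(c("f_nested", "cox_nonnested") %in% rep$comparisons$test))
  # every reported number is traceable to the fits
  expect_equal(rep$model_r2$r2_adj[3], rep$fits$III$r2_adj)
  expect_equal(rep$coefficients$estimate,
               unname(rep$fits$III$coefficients))
  expect_error(country_report(b[0, ], "SYN"), "empty")
  expect_error(country_report(b[, c("date", "y")], "SYN"), "missing")
  # CSV outputs
  dir <- tempfile()
  write_country_report(rep, dir)
  expect_setequal(list.files(dir),
                  c("correlations.csv", "model_r2.csv", "coefficients.csv"))
})
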