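#' Memory-kernel regression models of collective attention
#'
#' Collective online attention \eqn{y_t} (page views or comment volume) is
#' modeled from epidemic incidence and news volume with three nested-in-spirit
#' linear models:
#'
#' \deqn{\textrm{I:}\quad y_t = \alpha_1\,\textrm{incidence}_t + u_t}
#' \deqn{\textrm{II:}\quad y_t = \alpha_1\,\textrm{news}_t + u_t}
#' \deqn{\textrm{III:}\quad y_t = \alpha_1\,\textrm{news}_t +
#'       \alpha_2\,\textrm{newsMEM}_t + u_t}
#'
#' where the memory covariate is the exponentially decayed cumulative news
#' volume \eqn{\textrm{newsMEM}_t = \sum_{t' < t} \textrm{news}_{t'}
#' e^{-(t - t')/\tau}} with memory time scale \eqn{\tau}. A negative
#' \eqn{\alpha_2} quantifies attention *saturation*: sustained past exposure
#' depresses present response. \eqn{\tau} is tuned by refitting Model III
#' over a grid (integers 1 to 45 by default) and maximizing adjusted
#' \eqn{R^2}.
#'
#' @name attention-models
NULL

#' Exponentially decayed cumulative news volume
#'
#' Computes \eqn{\textrm{newsMEM}_t = \sum_{t' \in \textrm{past}(t)}
#' x_{t'}\, e^{-(t - t')/\tau}} on a regular (daily or weekly) grid. By
#' default the sum runs over strictly past steps (\eqn{t' < t}), so the
#' memory term stays distinguishable from the contemporaneous news
#' regressor; set `include_current_day = TRUE` to add the \eqn{t' = t} term
#' with unit weight. The operator is linear in its input.
#'
#' @param news Numeric vector (or tibble with a `value` column) on a regular
#'   time grid.
#' @param tau Positive memory time scale, in grid steps.
#' @param include_current_day Include the current step in the sum?
#' @return Numeric vector (or the input tibble with `value` replaced and
#'   `kind = "news_memory"`), same length and index as the input.
#' @export
#' @examples
#' build_memory_series(c(1, 0, 0), tau = 1) # c(0, exp(-1), exp(-2))
build_memory_series <- function(news, tau, include_current_day = FALSE) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive number")
  }
  x <- series_values(news, "news")
  n <- length(x)
  r <- exp(-1 / tau)
  m <- numeric(n)
  # recursion m[t] = r * (m[t-1] + x[t-1]) is the exact strictly-past sum
  for (t in seq_len(n)[-1]) m[t] <- r * (m[t - 1] + x[t - 1])
  if (include_current_day) m <- m + x
  if (is.data.frame(news)) {
    news$value <- m
    if ("kind" %in% names(news)) news$kind <- "news_memory"
    return(tibble::as_tibble(news))
  }
  m
}

# Core OLS through the stats QR path, with classical coefficient covariance.
ols_fit <- function(y, X, conf_level = 0.95) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort("need more observations than regressors (n > p + 1)")
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1, p)]]
    abort(paste("design is rank deficient; collinear regressor(s):",
                paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tstat <- beta / se
  list(coefficients = beta, se = se, statistic = tstat,
       p.value = 2 * pt(-abs(tstat), df),
       conf.low = beta - tcrit * se, conf.high = beta + tcrit * se,
       residuals = res, fitted = fit$fitted.values, rss = rss,
       n = n, p = p, df = df, sigma = sqrt(sigma2))
}

#' Fit one of the collective-attention models
#'
#' Ordinary least squares fit of Model I, II or III (see
#' [attention-models]). With `standardize = TRUE` every regressor is
#' z-scored before fitting; for Model III the memory covariate is built from
#' the z-scored news series and then itself z-scored, so its coefficient is
#' on the same scale as the news coefficient. With
#' `standardize_response = TRUE` (default) the response is z-scored too.
#' Standardized fits carry no intercept; unstandardized fits include one
#' unless `intercept = FALSE`.
#'
#' @param data Data frame holding the response and covariate series as
#'   columns on a shared regular time index.
#' @param model `"I"` (incidence), `"II"` (news) or `"III"` (news + memory).
#' @param response Name of the response column (default `"y"`).
#' @param tau Memory time scale; required for Model III.
#' @param include_current_day Passed to [build_memory_series()].
#' @param standardize Z-score the regressors (default `TRUE`).
#' @param standardize_response Z-score the response (default `standardize`).
#'   Leave `FALSE` when the response is already on the scale of the
#'   covariates, e.g. for coefficient-recovery studies on simulated data.
#' @param intercept Include an intercept column; default only when nothing
#'   is standardized.
#' @param conf_level Confidence level for coefficient intervals.
#' @return An object of class `attention_fit`: coefficients, classical 95%
#'   confidence intervals, residuals, RSS and adjusted \eqn{R^2}
#'   (`1 - (1 - R^2)(n - 1)/(n - p - 1)`). Methods: [tidy()], [glance()],
#'   [autoplot.attention_fit()].
#' @export
fit_attention_model <- function(data, model = c("III", "I", "II"),
                                response = "y", tau = NULL,
                                include_current_day = FALSE,
                                standardize = TRUE,
                                standardize_response = standardize,
                                intercept = !standardize && !standardize_response,
                                conf_level = 0.95) {
  model <- match.arg(model)
  vars <- switch(model, I = "incidence", II = "news", III = "news")
  miss <- setdiff(c(response, vars), names(data))
  if (length(miss)) abort(paste("missing column(s):", paste(miss, collapse = ", ")))
  y <- as.numeric(data[[response]])
  cols <- lapply(data[vars], as.numeric)
  if (standardize) cols <- lapply(cols, zscore_vec)
  if (model == "III") {
    if (is.null(tau)) abort("Model III needs `tau` for the memory covariate")
    mem <- build_memory_series(cols$news, tau, include_current_day)
    cols$news_mem <- if (standardize) zscore_vec(mem) else mem
  }
  if (standardize_response) y <- zscore_vec(y)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  fit <- ols_fit(y, X, conf_level)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - fit$rss / tss
  p_reg <- length(cols) # regressor count, intercept excluded
  fit$r2 <- r2
  fit$r2_adj <- 1 - (1 - r2) * (fit$n - 1) / (fit$n - p_reg - 1)
  fit$model <- model
  fit$tau <- tau
  fit$response <- y
  fit$design <- X
  fit$conf_level <- conf_level
  class(fit) <- "attention_fit"
  fit
}

#' @export
print.attention_fit <- function(x, ...) {
  cat("Collective-attention model", x$model,
      if (!is.null(x$tau)) paste0("(tau = ", x$tau, ")"), "\n")
  cat("  n =", x$n, " regressors =", ncol(x$design),
      " RSS =", signif(x$rss, 5), " adj R^2 =", signif(x$r2_adj, 4), "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of an attention model fit
#' @param x An `attention_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: estimate, standard error,
#'   t statistic, p value and confidence bounds.
#' @export
tidy.attention_fit <- function(x, ...) {
  tibble::tibble(
    term = colnames(x$design),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p.value),
    conf.low = unname(x$conf.low),
    conf.high = unname(x$conf.high)
  )
}

#' One-row model summary of an attention model fit
#' @param x An `attention_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model id, tau, R^2, adjusted R^2, RSS, sigma,
#'   n, residual df.
#' @export
glance.attention_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, tau = x$tau %||% NA_real_,
    r.squared = x$r2, adj.r.squared = x$r2_adj,
    rss = x$rss, sigma = x$sigma, nobs = x$n, df.residual = x$df
  )
}

#' Tune the memory time scale by adjusted R-squared
#'
#' Fits Model III at every candidate \eqn{\tau} and returns the value
#' maximizing adjusted \eqn{R^2}; ties go to the smallest \eqn{\tau}
#' (shortest memory consistent with the data). The full profile is returned
#' for diagnostics.
#'
#' @param data Data frame with the response and `news` columns.
#' @param grid Strictly increasing vector of positive candidate time scales
#'   (default integers 1 to 45).
#' @inheritParams fit_attention_model
#' @param ... Further arguments passed to [fit_attention_model()].
#' @return An object of class `tau_profile`: `tau_best`, the winning
#'   `attention_fit` (`fit`), and a tibble `profile` of (tau, r2_adj).
#' @export
tune_tau <- function(data, grid = 1:45, response = "y", ...) {
  if (length(grid) == 0 || any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be non-empty, positive and strictly increasing")
  }
  fits <- lapply(grid, function(tau) {
    fit_attention_model(data, model = "III", response = response, tau = tau, ...)
  })
  r2a <- vapply(fits, function(f) f$r2_adj, numeric(1))
  best <- which.max(r2a) # which.max returns the first (smallest-tau) maximum
  structure(
    list(tau_best = grid[best], fit = fits[[best]],
         profile = tibble::tibble(tau = grid, r2_adj = r2a)),
    class = "tau_profile"
  )
}

#' @export
print.tau_profile <- function(x, ...) {
  cat("Memory time-scale profile over", nrow(x$profile), "candidates\n")
  cat("  best tau =", x$tau_best, "with adj R^2 =",
      signif(max(x$profile$r2_adj), 4), "\n")
  invisible(x)
}

#' F test for nested attention models
#'
#' Compares a restricted model to a full model containing its regressors
#' (typically Model II against Model III) with
#' \deqn{F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_f)/(p_f - p_r)}
#'            {\mathrm{RSS}_f/(n - p_f)}}
#' referred to the \eqn{F(p_f - p_r,\; n - p_f)} distribution.
#'
#' @param fit_restricted,fit_full `attention_fit` objects on the same
#'   response, the restricted design a strict subset of the full one.
#' @param alpha Significance level used to call a winner (default 0.05).
#' @return A tibble of class `model_comparison`: test, statistic, df,
#'   p.value, winner.
#' @export
f_test_nested <- function(fit_restricted, fit_full, alpha = 0.05) {
  nr <- fit_restricted$n; nf <- fit_full$n
  if (nr != nf) abort("fits must share the same response (n differs)")
  terms_r <- colnames(fit_restricted$design)
  terms_f <- colnames(fit_full$design)
  if (!all(terms_r %in% terms_f) || length(terms_f) <= length(terms_r)) {
    abort("models are not nested: restricted terms must be a strict subset")
  }
  pr <- ncol(fit_restricted$design); pf <- ncol(fit_full$design)
  df1 <- pf - pr; df2 <- nf - pf
  fstat <- ((fit_restricted$rss - fit_full$rss) / df1) / (fit_full$rss / df2)
  fstat <- max(fstat, 0)
  pval <- pf(fstat, df1, df2, lower.tail = FALSE)
  out <- tibble::tibble(
    test = "f_nested", statistic = fstat, df1 = df1, df2 = df2,
    p.value = pval,
    winner = if (pval < alpha) fit_full$model else fit_restricted$model
  )
  class(out) <- c("model_comparison", class(out))
  out
}

# residual maker: y - X (X'X)^-1 X' y, via QR
resid_on <- function(M, X) {
  qrx <- qr(X)
  M - qr.fitted(qrx, M)
}

is_nested_in <- function(A, B, tol = 1e-8) {
  # every column of A lies in the column space of B
  r <- resid_on(A, B)
  sqrt(sum(r^2)) < tol * max(1, sqrt(sum(A^2)))
}

cox_one_direction <- function(y, X1, X2) {
  n <- length(y)
  e0 <- resid_on(y, X1)
  e1 <- resid_on(y, X2)
  s0_2 <- sum(e0^2) / n
  s1_2 <- sum(e1^2) / n
  yhat0 <- y - e0
  q <- resid_on(yhat0, X2)      # part of model-1 fit unexplained by model 2
  s10_2 <- s0_2 + sum(q^2) / n  # predicted model-2 variance under H0
  c01 <- (n / 2) * log(s1_2 / s10_2)
  v <- s0_2 * sum(resid_on(q, X1)^2) / s10_2^2
  stat <- c01 / sqrt(v)
  c(statistic = stat, p.value = 2 * pnorm(-abs(stat)))
}

#' Cox test for non-nested attention models
#'
#' Compares two linear models whose regressor sets do not contain one
#' another (typically Model I against Model III) with the classical Cox
#' statistic in its variance-comparison form: the difference between the
#' alternative model's fitted log-variance and its expectation under the
#' null model, studentized by its estimated standard error. The statistic is
#' asymptotically standard normal under the null that the first model is
#' correct; the test is run in both directions.
#'
#' @param y Numeric response vector (or tibble with a `value` column).
#' @param X1,X2 Design matrices (or data frames) of the two candidate
#'   models, neither nested in the other.
#' @param alpha Significance level used to call a winner (default 0.05).
#' @return A tibble of class `model_comparison` with one row per direction
#'   (`null` = the model taken as correct), statistic, two-sided p.value,
#'   and a common `winner`: the model whose null is not rejected when the
#'   other's is, otherwise `"none"`.
#' @export
cox_test_nonnested <- function(y, X1, X2, alpha = 0.05) {
  y <- series_values(y, "y")
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (is_nested_in(X1, X2) || is_nested_in(X2, X1)) {
    abort("designs are nested (or identical); use f_test_nested() instead")
  }
  d12 <- cox_one_direction(y, X1, X2)
  d21 <- cox_one_direction(y, X2, X1)
  rej <- c(d12["p.value"], d21["p.value"]) < alpha
  winner <- if (rej[1] && !rej[2]) "model2"
            else if (rej[2] && !rej[1]) "model1"
            else "none"
  out <- tibble::tibble(
    test = "cox_nonnested",
    null = c("model1", "model2"),
    statistic = c(d12[["statistic"]], d21[["statistic"]]),
    p.value = c(d12[["p.value"]], d21[["p.value"]]),
    winner = winner
  )
  class(out) <- c("model_comparison", class(out))
  out
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson correlation with the classical t-based two-sided test
#' (`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom), as used for
#' country-level correlation tables between news volume, incidence and
#' attention signals.
#'
#' @param x,y Numeric vectors (or tibbles with a `value` column) of equal
#'   length at least 3, each with nonzero variance.
#' @return A one-row tibble: `r`, `p.value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  x <- series_values(x, "x"); y <- series_values(y, "y")
  if (length(x) != length(y)) abort("series must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Per-country attention report
#'
#' Runs the full country-level analysis on a bundle of aligned daily series:
#' pairwise Pearson correlations, all three attention models (Model III at
#' the tuned memory time scale), their adjusted \eqn{R^2}, the nested F and
#' non-nested Cox comparisons, and the Model III coefficient table with
#' confidence intervals.
#'
#' @param data Data frame with aligned columns `incidence`, `news` and the
#'   response column, one row per time step.
#' @param country Country label carried into the output tables.
#' @param response Name of the response column (default `"y"`).
#' @param tau_grid Candidate memory time scales (default 1:45).
#' @param ... Passed to [fit_attention_model()] / [tune_tau()].
#' @return A list of class `country_report`: tibbles `correlations`,
#'   `model_r2`, `coefficients`, `comparisons`, plus `tau_best` and the
#'   three fits.
#' @export
country_report <- function(data, country = "country", response = "y",
                           tau_grid = 1:45, ...) {
  need <- c("incidence", "news", response)
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("bundle incomplete; missing:", paste(miss, collapse = ", ")))
  if (nrow(data) == 0) abort("bundle is empty")

  pairs <- list(
    c("news", "incidence"), c("news", response), c("incidence", response)
  )
  correlations <- purrr::map_dfr(pairs, function(p) {
    dplyr::mutate(pearson_with_p(data[[p[1]]], data[[p[2]]]),
                  country = country, var1 = p[1], var2 = p[2],
                  .before = 1)
  })

  fit1 <- fit_attention_model(data, "I", response = response, ...)
  fit2 <- fit_attention_model(data, "II", response = response, ...)
  prof <- tune_tau(data, grid = tau_grid, response = response, ...)
  fit3 <- prof$fit

  model_r2 <- tibble::tibble(
    country = country, model = c("I", "II", "III"),
    tau = c(NA, NA, prof$tau_best),
    r2_adj = c(fit1$r2_adj, fit2$r2_adj, fit3$r2_adj)
  )
  coefficients <- dplyr::mutate(tidy(fit3), country = country,
                                model = "III", tau = prof$tau_best,
                                .before = 1)
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(f_test_nested(fit2, fit3),
                  null = "II", alternative = "III", country = country),
    dplyr::mutate(cox_test_nonnested(fit3$response, fit1$design, fit3$design),
                  alternative = "I vs III", country = country)
  )
  structure(
    list(correlations = correlations, model_r2 = model_r2,
         coefficients = coefficients, comparisons = comparisons,
         tau_best = prof$tau_best, tau_profile = prof,
         fits = list(I = fit1, II = fit2, III = fit3)),
    class = "country_report"
  )
}

#' @export
print.country_report <- function(x, ...) {
  cat("Country attention report (tau* =", x$tau_best, ")\n\nAdjusted R^2:\n")
  print(x$model_r2)
  cat("\nModel III coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' Write the report tables of a country report as CSV
#'
#' Emits `correlations.csv`, `model_r2.csv` and `coefficients.csv` in `dir`.
#'
#' @param report A `country_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_country_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model_r2, file.path(dir, "model_r2.csv"),
                   row.names = FALSE)
  utils::write.csv(report$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  invisible(dir)
}
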