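#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot observed versus fitted attention
#'
#' @param object An `attention_fit`.
#' @param ... Unused.
#' @return A ggplot: observed (points) and fitted (line) standardized
#'   attention over the time index, with residual context in the subtitle.
#' @export
autoplot.attention_fit <- function(object, ...) {
  df <- tibble::tibble(t = seq_along(object$response),
                       observed = object$response, fitted = object$fitted)
  ggplot(df, aes(x = .data$t)) +
    geom_point(aes(y = .data$observed), colour = "grey40", size = 0.9) +
    geom_line(aes(y = .data$fitted), colour = "#2166ac") +
    labs(title = paste("Attention model", object$model),
         subtitle = paste0("adj R² = ", signif(object$r2_adj, 3),
                           if (!is.null(object$tau)) paste0(", τ = ", object$tau)),
         x = "time step", y = "attention (standardized)") +
    theme_minimal()
}

#' Plot the memory time-scale profile
#'
#' @param object A `tau_profile` from [tune_tau()].
#' @param ... Unused.
#' @return A ggplot of adjusted R-squared against the candidate
#'   \eqn{\tau}, with the selected value marked.
#' @export
autoplot.tau_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$tau, y = .data$r2_adj)) +
    geom_line(colour = "grey50") +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$tau_best, linetype = 2, colour = "#b2182b") +
    labs(title = "Memory time-scale tuning",
         subtitle = paste("selected τ =", object$tau_best),
         x = "τ (days)", y = "adjusted R²") +
    theme_minimal()
}

#' Plot daily topic strengths
#'
#' @param object A `topic_strengths` tibble.
#' @param topics Optional subset of topic ids to show.
#' @param ... Unused.
#' @return A ggplot of \eqn{s_k(t)} faceted by topic.
#' @export
autoplot.topic_strengths <- function(object, topics = NULL, ...) {
  df <- if (is.null(topics)) object else object[object$topic %in% topics, ]
  ggplot(df, aes(x = .data$date, y = .data$strength)) +
    geom_line(colour = "#2166ac") +
    facet_wrap(~topic, scales = "free_y") +
    labs(x = NULL, y = "topic strength s_k(t)") +
    theme_minimal()
}

#' Plot interest-share differences between two sources
#'
#' @param diffs Tibble from [interest_share_diff()].
#' @param label1,label2 Source labels for the axis annotation.
#' @return A ggplot bar chart of per-topic share differences (percentage
#'   points); bars above zero mark topics source 1 favours.
#' @export
plot_interest_shares <- function(diffs, label1 = "source 1", label2 = "source 2") {
  diffs$topic <- factor(diffs$topic, levels = diffs$topic[order(diffs$diff)])
  ggplot(diffs, aes(x = .data$topic, y = .data$diff)) +
    geom_col(fill = "#2166ac") +
    geom_hline(yintercept = 0, colour = "grey30") +
    labs(x = NULL,
         y = paste0("share(", label1, ") − share(", label2, ") [pp]")) +
    theme_minimal() +
    ggplot2::coord_flip()
}

#' Plot half-relevance times of two sources against each other
#'
#' Topics below the diagonal reached half their relevance earlier in source
#' 2 than in source 1.
#'
#' @param half1,half2 Tibbles from [topic_half_time()] for the two sources.
#' @param label1,label2 Axis labels.
#' @return A ggplot scatter of per-topic half-relevance dates.
#' @export
plot_half_times <- function(half1, half2, label1 = "source 1",
                            label2 = "source 2") {
  df <- dplyr::inner_join(half1, half2, by = "topic",
                          suffix = c("_1", "_2"))
  ggplot(df, aes(x = .data$t_half_1, y = .data$t_half_2)) +
    geom_point(colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = 2, colour = "grey50") +
    labs(x = paste("t½ in", label1), y = paste("t½ in", label2)) +
    theme_minimal()
}
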