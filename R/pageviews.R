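#' Country-attributed page-view volumes
#'
#' Page-view dumps report daily visits to an article from a *project* (a
#' language edition) without saying which country they came from. Because a
#' shared language spreads one project's traffic over several countries, the
#' daily per-article signal is weighted by the share of the project's total
#' monthly views originating from the country of interest:
#'
#' \deqn{v_{a,p,c}(d) = S_{a,p}(d) \cdot
#'       \frac{\sigma_{p,c}(m(d))}{\sigma_p(m(d))}}
#'
#' where \eqn{S_{a,p}(d)} is the raw daily view count of article *a* on
#' project *p*, \eqn{\sigma_{p,c}(m)} the project's monthly views from
#' country *c* in the calendar month \eqn{m(d)} containing *d*, and
#' \eqn{\sigma_p(m)} the project's total monthly views. The country's daily
#' attention volume is then the sum over all articles and projects.
#'
#' @name pageviews
NULL

month_key <- function(date) format(date, "%Y-%m")

# monthly: tibble project, country, month ("YYYY-MM" or Date), views.
# Rows with country == "__total__" carry the per-project monthly totals.
monthly_weights <- function(monthly, country) {
  monthly$month <- if (inherits(monthly$month, "Date")) {
    month_key(monthly$month)
  } else {
    substr(as.character(monthly$month), 1, 7)
  }
  totals <- monthly[monthly$country == "__total__", c("project", "month", "views")]
  names(totals)[3] <- "total"
  mine <- monthly[monthly$country == country, c("project", "month", "views")]
  names(mine)[3] <- "country_views"
  w <- dplyr::left_join(totals, mine, by = c("project", "month"))
  w$country_views[is.na(w$country_views)] <- 0
  bad <- w$country_views > w$total
  if (any(bad)) {
    abort(paste0("country monthly views exceed project total for ",
                 w$project[bad][1], " ", w$month[bad][1]))
  }
  w$weight <- ifelse(w$total > 0, w$country_views / w$total, NA_real_)
  w
}

#' Normalize one article-day view count to a country
#'
#' @param views Nonnegative raw daily views of one article from one project.
#' @param country_views The project's monthly views from the target country.
#' @param total_views The project's total monthly views (must be positive).
#' @return `views * country_views / total_views`, a value in `[0, views]`.
#' @export
#' @examples
#' normalize_article_views(10, 1000, 4000) # 2.5
normalize_article_views <- function(views, country_views, total_views) {
  if (any(!is.finite(total_views)) || any(total_views <= 0)) {
    abort("monthly project total must be positive to normalize views")
  }
  if (any(country_views > total_views)) {
    abort("country monthly views cannot exceed the project total")
  }
  views * country_views / total_views
}

#' Aggregate article-level page views into a country's daily volume
#'
#' Each (article, project, date) record is weighted by the project's monthly
#' country share (see [pageviews]) and summed per day. Dates inside the
#' window with no records yield 0 (sparse dumps omit zero rows).
#'
#' @param views Tibble with columns `article`, `project`, `date`, `views`.
#' @param monthly Tibble with columns `project`, `country`, `month`, `views`;
#'   rows with `country == "__total__"` hold per-project monthly totals.
#' @param country Country code whose volume is wanted.
#' @param window Optional `Date` vector of length 2 giving the analysis
#'   window; defaults to the range of `views$date`.
#' @return Tibble `country`, `date`, `kind = "pageviews"`, `value` with one
#'   row per day of the window.
#' @export
country_daily_volume <- function(views, monthly, country, window = NULL) {
  if (is.null(window)) {
    if (nrow(views) == 0) abort("empty views table needs an explicit `window`")
    window <- range(views$date)
  }
  days <- seq(window[1], window[2], by = "day")
  out <- tibble::tibble(country = country, date = days,
                        kind = "pageviews", value = 0)
  if (nrow(views) == 0) return(out)
  w <- monthly_weights(monthly, country)
  views$month <- month_key(views$date)
  v <- dplyr::left_join(views, w[, c("project", "month", "weight")],
                        by = c("project", "month"))
  if (anyNA(v$weight)) {
    miss <- v[is.na(v$weight), c("project", "month")]
    abort(paste0("no (or zero-total) monthly views for project ",
                 miss$project[1], " in month ", miss$month[1]))
  }
  daily <- v |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(value = sum(.data$views * .data$weight), .groups = "drop")
  idx <- match(daily$date, out$date)
  keep <- !is.na(idx)
  out$value[idx[keep]] <- daily$value[keep]
  out
}

#' Sum a daily series into ISO weeks
#'
#' Weeks run Monday to Sunday and are labeled by their Monday. Edge weeks not
#' fully covered by the input dates are retained but flagged `partial`.
#' Total mass is conserved: the weekly values sum to the daily values.
#'
#' @param series Tibble with columns `date` and `value` (daily resolution);
#'   `country` and `kind` columns are carried through if present.
#' @return Tibble `date` (week's Monday), `value`, `n_days`, `partial`.
#' @export
weekly_aggregate <- function(series) {
  carry <- intersect(c("country", "kind"), names(series))
  if (nrow(series) == 0) {
    return(tibble::tibble(date = as.Date(character()), value = numeric(),
                          n_days = integer(), partial = logical()))
  }
  wd <- as.integer(format(series$date, "%u")) # 1 = Monday
  monday <- series$date - (wd - 1)
  out <- series |>
    dplyr::mutate(week = monday) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(carry)), date = .data$week) |>
    dplyr::summarise(value = sum(.data$value), n_days = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$date)
  out$partial <- out$n_days < 7L
  out
}
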