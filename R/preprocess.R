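# Gap handling and calendar alignment. Daily series are tibbles with
# columns `date` and `value`; a gap is an NA value (or an absent date inside
# the span, which is completed to an NA row first).

#' Seasonal-split imputation of a daily series
#'
#' Fills gaps while preserving weekly seasonality: the series is split into
#' `period` subseries (for the default period of 7, one per calendar
#' weekday), and within each subseries missing values are filled by linear
#' interpolation between the nearest observed neighbours. Leading and
#' trailing gaps, where interpolation is undefined, take the nearest
#' observation within the same subseries. Observed values are never changed.
#'
#' @param series Tibble with columns `date` and `value`; gaps are `NA`
#'   values (readers and the generator already materialise absent days as
#'   `NA` rows). Dates not present in the input are not invented.
#' @param period Length of the seasonal cycle in days (default 7).
#' @return The series with every `NA` filled, with attribute `n_imputed`
#'   giving the number of filled days.
#' @export
impute_seasonal_split <- function(series, period = 7L) {
  stopifnot(is.numeric(period), length(period) == 1L, period >= 1)
  check_daily_series(series)
  out <- arrange(series[c("date", "value")], .data$date)
  if (!nrow(out) || !anyNA(out$value)) {
    attr(out, "n_imputed") <- 0L
    return(out)
  }
  if (period == 7L) {
    grp <- weekday_index(out$date)
    grp_name <- function(g) .weekday_labels[g]
  } else {
    grp <- as.integer(out$date - min(out$date)) %% as.integer(period) + 1L
    grp_name <- function(g) sprintf("cycle position %d", g)
  }
  n_imputed <- sum(is.na(out$value))
  t <- as.numeric(out$date)
  value <- out$value
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    obs <- idx[!is.na(value[idx])]
    if (!anyNA(value[idx])) next
    if (length(obs) == 0L) {
      abort(sprintf("cannot impute: no observed values for %s", grp_name(g)))
    }
    if (length(obs) == 1L) {
      value[idx] <- value[obs]
    } else {
      value[idx] <- approx(t[obs], value[obs], xout = t[idx], rule = 2)$y
    }
  }
  out$value <- value
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Matched previous-year interval
#'
#' Returns the same calendar-day interval one year earlier, as used to
#' compare each lockdown window against the pre-pandemic year. An endpoint
#' of 29 February rolls back to 28 February; for paired day-by-day
#' comparisons use [matched_days()], which drops leap days.
#'
#' @param start,end Interval endpoints (inclusive), `Date` or ISO strings.
#' @return A list with elements `start` and `end`.
#' @export
match_previous_year <- function(start, end) {
  start <- as_iso_date(start, "start")
  end <- as_iso_date(end, "end")
  if (start > end) abort("`start` must not be after `end`")
  list(start = start %m-% lubridate::years(1),
       end = end %m-% lubridate::years(1))
}

#' @importFrom lubridate %m-%
NULL

#' Day-by-day pairing of an interval with its previous-year match
#'
#' Pairs every day of the interval with the same calendar day one year
#' earlier. 29 February has no match and is excluded from both sides.
#'
#' @inheritParams match_previous_year
#' @return A tibble with columns `current` and `reference` (both `Date`).
#' @export
matched_days <- function(start, end) {
  start <- as_iso_date(start, "start")
  end <- as_iso_date(end, "end")
  if (start > end) abort("`start` must not be after `end`")
  cur <- seq(start, end, by = "day")
  cur <- cur[!(lubridate::month(cur) == 2 & lubridate::mday(cur) == 29)]
  ref <- as.Date(sprintf("%d-%02d-%02d", lubridate::year(cur) - 1L,
                         lubridate::month(cur), lubridate::mday(cur)))
  tibble(current = cur, reference = ref)
}

#' Weekly means of a daily series
#'
#' Groups by ISO week and averages the observed (post-imputation) days in
#' each week; partial boundary weeks average over their available days.
#'
#' @param series Tibble with columns `date` and `value`.
#' @return A tibble with columns `week_start` (the Monday of each ISO week),
#'   `n_days`, and `mean`.
#' @export
weekly_mean <- function(series) {
  check_daily_series(series)
  out <- mutate(series,
                week_start = lubridate::floor_date(.data$date, "week", week_start = 1))
  out <- summarise(group_by(out, .data$week_start),
                   n_days = sum(!is.na(.data$value)),
                   mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  out$mean[is.nan(out$mean)] <- NA_real_
  arrange(out, .data$week_start)
}
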