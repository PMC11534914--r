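# Lockdown-period reporting: per-period daily averages against the matched
# previous-year interval, and the rendered correlation table.

#' Austrian hard-lockdown period presets
#'
#' Three hard lockdowns fall in the study window 2019-01-01 to 2021-02-08.
#' Two presets are shipped because the sources differ by one day on the
#' first lockdown's start: `"published"` uses 16 March 2020 (the interval the
#' published summary table is computed on) and `"announced"` uses the
#' announced start of 15 March 2020. Each period carries its matched
#' previous-year reference interval.
#'
#' @param preset `"published"` (default) or `"announced"`.
#' @return A tibble with columns `name`, `start`, `end`, `ref_start`,
#'   `ref_end` (all intervals inclusive).
#' @export
lockdown_periods <- function(preset = c("published", "announced")) {
  preset <- match.arg(preset)
  first_start <- if (preset == "published") "2020-03-16" else "2020-03-15"
  out <- tibble(
    name = c("first", "second", "third"),
    start = as.Date(c(first_start, "2020-11-17", "2020-12-26")),
    end = as.Date(c("2020-04-30", "2020-12-06", "2021-02-07"))
  )
  ref <- lapply(seq_len(nrow(out)),
                function(i) match_previous_year(out$start[i], out$end[i]))
  out$ref_start <- as.Date(vapply(ref, function(r) format(r$start), character(1)))
  out$ref_end <- as.Date(vapply(ref, function(r) format(r$end), character(1)))
  out
}

#' Average outpatients per day over a period
#'
#' Total selected counts divided by the number of days in the period.
#' When the period takes part in a matched previous-year comparison, leap
#' days are excluded (`drop_leap = TRUE`) so both intervals cover the same
#' calendar days.
#'
#' @param series Tibble with columns `date` and `value`; the period must lie
#'   within its span. Imputed days participate like observed ones.
#' @param start,end Period endpoints, inclusive.
#' @param drop_leap Exclude 29 February from the period.
#' @return The mean daily count (a scalar).
#' @export
average_outpatients_per_day <- function(series, start, end, drop_leap = FALSE) {
  check_daily_series(series)
  start <- as_iso_date(start, "start")
  end <- as_iso_date(end, "end")
  if (start > end) abort("empty period: `start` after `end`")
  if (!nrow(series) || start < min(series$date) || end > max(series$date)) {
    abort(sprintf("period %s..%s not covered by series span",
                  format(start), format(end)))
  }
  days <- seq(start, end, by = "day")
  if (drop_leap) {
    days <- days[!(lubridate::month(days) == 2 & lubridate::mday(days) == 29)]
  }
  v <- series$value[match(days, series$date)]
  if (anyNA(v)) {
    warn(sprintf("%d unobserved day(s) in period %s..%s excluded from the denominator",
                 sum(is.na(v)), format(start), format(end)))
  }
  sum(v, na.rm = TRUE) / sum(!is.na(v))
}

#' Percent difference to a reference, rounded half away from zero
#'
#' `100 * (current - reference) / reference`, rounded to integer percent
#' with ties going away from zero (the convention under which the published
#' summary cells recompute from their per-day averages).
#'
#' @param current,reference Nonnegative reals; `reference` must be positive.
#' @return Signed integer percent (vectorised).
#' @export
percent_diff <- function(current, reference) {
  if (any(reference <= 0)) abort("`reference` must be positive")
  as.integer(round_half_away(100 * (current - reference) / reference))
}

#' Lockdown summary table
#'
#' One row per city, sex selector (female, male, total) and lockdown
#' period, with the average outpatients per day in the period and in its
#' matched previous-year interval, and their rounded percent difference.
#' Totals are formed per day as female + male before averaging, so the
#' total AO/d equals the sum of the sex-specific ones exactly
#' (pre-rounding).
#'
#' @param counts Tibble with columns `city`, `date`, `sex`, `count`
#'   (post-imputation; gaps would otherwise shrink the denominators).
#' @param periods A [lockdown_periods()]-style tibble.
#' @return A tibble with columns `city`, `period`, `sex`, `ao_d_ref`,
#'   `ao_d_cur`, `diff_pct`.
#' @export
lockdown_table <- function(counts, periods) {
  cities <- sort(unique(counts$city))
  rows <- list()
  for (ct in cities) {
    per_sex <- list(
      female = filter(counts, .data$city == ct, .data$sex == "female") %>%
        rename(value = "count"),
      male = filter(counts, .data$city == ct, .data$sex == "male") %>%
        rename(value = "count"),
      total = outpatient_totals(filter(counts, .data$city == ct))
    )
    for (i in seq_len(nrow(periods))) {
      for (sx in names(per_sex)) {
        cur <- average_outpatients_per_day(per_sex[[sx]], periods$start[i],
                                           periods$end[i], drop_leap = TRUE)
        ref <- average_outpatients_per_day(per_sex[[sx]], periods$ref_start[i],
                                           periods$ref_end[i], drop_leap = TRUE)
        rows[[length(rows) + 1L]] <- tibble(
          city = ct, period = periods$name[i], sex = sx,
          ao_d_ref = ref, ao_d_cur = cur,
          diff_pct = percent_diff(cur, ref))
      }
    }
  }
  bind_rows(rows)
}

#' Correlation table across cities
#'
#' Assembles per-city correlation results and the pooled "All cities" row
#' into one table, flagging significance at the result's own alpha.
#'
#' @param per_city Named list of one-row tibbles from [pearson_corr()].
#' @param pooled One-row tibble from [pearson_corr()] on the pooled pairs.
#' @param provider Label for the mobility data provider column.
#' @return A tibble with columns `provider`, `region`, `r`, `ci_low`,
#'   `ci_high`, `p`, `n`, `significant`.
#' @export
correlation_table <- function(per_city, pooled, provider = "Google") {
  rows <- bind_rows(c(per_city, list(`All cities` = pooled)), .id = "region")
  out <- mutate(rows, provider = provider, significant = .data$p < .data$alpha)
  out[c("provider", "region", "r", "ci_low", "ci_high", "p", "n", "significant")]
}

#' Render a correlation table for reporting
#'
#' Applies the reporting rounding convention: r and interval bounds to two
#' decimals, p-values below 0.001 shown as `"<0.001"`.
#'
#' @param tbl A [correlation_table()] result.
#' @return A tibble of formatted strings with columns `provider`, `region`,
#'   `r`, `ci_95`, `p_value`.
#' @export
format_correlation_table <- function(tbl) {
  tibble(provider = tbl$provider, region = tbl$region,
         r = sprintf("%.2f", tbl$r),
         ci_95 = sprintf("%.2f; %.2f", tbl$ci_low, tbl$ci_high),
         p_value = ifelse(tbl$p < 0.001, "<0.001", sprintf("%.3f", tbl$p)))
}
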