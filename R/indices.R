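# Composite index construction. All indices are expressed in percentage
# points relative to a baseline: 0 means baseline-level activity.

#' Leisure-related mobility index
#'
#' Composite of the four Google location categories tied to discretionary
#' movement: the mean of retail/recreation, parks and transit
#' percent-change-from-baseline minus the residential one, divided by four.
#' Residential enters with a negative weight because time spent at home
#' reflects compliance with movement restrictions; grocery/pharmacy
#' (essential activity) and workplaces (confounded by remote work) are
#' excluded.
#'
#' @param cfb_rr,cfb_pa,cfb_ts,cfb_res Percent change from baseline for the
#'   retail/recreation, parks, transit and residential categories
#'   (vectorised; `NA` in any argument yields `NA`).
#' @return Numeric vector of index values in percentage points.
#' @export
leisure_mobility_index <- function(cfb_rr, cfb_pa, cfb_ts, cfb_res) {
  (cfb_rr + cfb_pa + cfb_ts - cfb_res) / 4
}

#' Leisure mobility index series from a Google-style mobility table
#'
#' @param google Tibble as returned by [read_google_csv()].
#' @return A tibble with columns `region`, `date`, `value` (the index; `NA`
#'   where any of the four categories is missing).
#' @export
mobility_index <- function(google) {
  out <- mutate(google, value = leisure_mobility_index(
    .data$retail_recreation, .data$parks, .data$transit, .data$residential))
  arrange(out[c("region", "date", "value")], .data$region, .data$date)
}

#' Percent change from baseline for Apple-style mobility data
#'
#' Apple-style values are baseline-indexed volumes (100 = the baseline
#' day); the percent change of each transportation type is `value - 100`,
#' and types available on a date are combined by unweighted mean.
#'
#' @param apple Long tibble as returned by [read_apple_csv()].
#' @return A tibble with columns `region`, `date`, `value` (`NA` on dates
#'   where every type is missing).
#' @export
apple_cfb <- function(apple) {
  out <- summarise(group_by(apple, .data$region, .data$date),
                   value = if (all(is.na(.data$value))) NA_real_
                           else mean(.data$value - 100, na.rm = TRUE),
                   .groups = "drop")
  arrange(out, .data$region, .data$date)
}

#' Per-weekday median baseline
#'
#' Medians of a daily series by calendar weekday over a reference window,
#' mirroring the construction of the provider baselines (each day is
#' compared against the typical level of its own weekday). Even-sized
#' weekday samples use the mean of the two central order statistics.
#'
#' @param series Tibble with columns `date` and `value`.
#' @param window Length-2 vector (start, end) of the reference window,
#'   inclusive.
#' @return A tibble with columns `weekday` (1 = Monday), `label`, `median`.
#' @export
weekday_median_baseline <- function(series, window) {
  check_daily_series(series)
  start <- as_iso_date(window[[1]], "window start")
  end <- as_iso_date(window[[2]], "window end")
  sub <- filter(series, .data$date >= start, .data$date <= end, !is.na(.data$value))
  wd <- weekday_index(sub$date)
  med <- vapply(1:7, function(g) {
    v <- sub$value[wd == g]
    if (!length(v)) {
      abort(sprintf("reference window has no observation for %s", .weekday_labels[g]))
    }
    median(v)
  }, numeric(1))
  tibble(weekday = 1:7, label = .weekday_labels, median = med)
}

#' Averaged outpatient index, per-weekday-median baseline convention
#'
#' Percent change of daily counts against a per-weekday median baseline:
#' `100 * (count - baseline[weekday]) / baseline[weekday]`. This mirrors
#' the Google mobility baseline convention.
#'
#' @param counts Tibble with columns `date` and `value` (daily counts).
#' @param baseline A [weekday_median_baseline()] table with all medians
#'   positive.
#' @return A tibble with columns `date`, `value` (index in percentage
#'   points).
#' @export
aoi_google <- function(counts, baseline) {
  check_daily_series(counts, "counts")
  if (any(baseline$median <= 0)) {
    abort(sprintf("baseline median for %s is not positive",
                  baseline$label[which(baseline$median <= 0)[1]]))
  }
  b <- baseline$median[match(weekday_index(counts$date), baseline$weekday)]
  tibble(date = counts$date, value = 100 * (counts$value - b) / b)
}

#' Averaged outpatient index, single-baseline-day convention
#'
#' Percent change of daily counts against the count observed on one
#' reference date, mirroring the Apple mobility baseline convention
#' (13 January 2020 in the original feeds).
#'
#' @param counts Tibble with columns `date` and `value` (daily counts).
#' @param baseline_date The reference date; its count must be observed and
#'   positive.
#' @return A tibble with columns `date`, `value`.
#' @export
aoi_apple <- function(counts, baseline_date) {
  check_daily_series(counts, "counts")
  baseline_date <- as_iso_date(baseline_date, "baseline_date")
  b <- counts$value[match(baseline_date, counts$date)]
  if (length(b) != 1L || is.na(b)) {
    abort(sprintf("no observed count at baseline date %s", format(baseline_date)))
  }
  if (b <= 0) abort("baseline-date count must be positive")
  tibble(date = counts$date, value = 100 * (counts$value - b) / b)
}
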