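# In-code fixture builders for the three CSV dialects.

`%m+%` <- lubridate::`%m+%`
`%m-%` <- lubridate::`%m-%`

google_header <- paste(
  "country_region,sub_region_1,date",
  "retail_and_recreation_percent_change_from_baseline",
  "grocery_and_pharmacy_percent_change_from_baseline",
  "parks_percent_change_from_baseline",
  "transit_stations_percent_change_from_baseline",
  "workplaces_percent_change_from_baseline",
  "residential_percent_change_from_baseline", sep = ",")

write_google_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(google_header, rows), path)
  path
}

write_apple_fixture <- function(dates, rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(paste(c("geo_type,region,transportation_type", dates), collapse = ","),
               rows), path)
  path
}

write_outpatients_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("city,date,sex,count", rows), path)
  path
}

daily_series <- function(dates, values) {
  tibble::tibble(date = as.Date(dates), value = values)
}

# Constant-by-period count series covering both lockdown windows and their
# previous-year references, for table-reconstruction checks.
constant_period_counts <- function(city, periods, ref_values, cur_values, sex = "female") {
  days <- seq(as.Date("2019-01-01"), as.Date("2021-02-08"), by = "day")
  value <- rep(1, length(days))
  for (i in seq_len(nrow(periods))) {
    value[days >= periods$ref_start[i] & days <= periods$ref_end[i]] <- ref_values[i]
    value[days >= periods$start[i] & days <= periods$end[i]] <- cur_values[i]
  }
  tibble::tibble(city = city, date = days, sex = sex, count = value)
}
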