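# Readers and writers for the three CSV dialects the pipeline consumes:
# Google-style long mobility reports, Apple-style wide mobility trends, and
# the package's own daily outpatient count format. Readers validate headers
# and values and never invent data: empty cells come back as NA.

# canonical internal name -> provider column name
google_category_cols <- c(
  retail_recreation = "retail_and_recreation_percent_change_from_baseline",
  grocery_pharmacy  = "grocery_and_pharmacy_percent_change_from_baseline",
  parks             = "parks_percent_change_from_baseline",
  transit           = "transit_stations_percent_change_from_baseline",
  workplaces        = "workplaces_percent_change_from_baseline",
  residential       = "residential_percent_change_from_baseline"
)

#' Names of the six Google mobility location categories
#'
#' @return Character vector of the canonical internal column names used for
#'   the six percent-change-from-baseline location categories.
#' @export
mobility_categories <- function() names(google_category_cols)

read_csv_chr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE, show_col_types = FALSE)
}

parse_num_cell <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    abort(sprintf("column `%s`: non-numeric value '%s' at data row %d",
                  column, x[bad[1]], bad[1]))
  }
  out[x == ""] <- NA_real_
  out
}

parse_date_col <- function(x, column) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out))
  if (length(bad)) {
    # +1 for the header line so the message points at the file line
    abort(sprintf("column `%s`: unparseable date '%s' at line %d",
                  column, x[bad[1]], bad[1] + 1L))
  }
  out
}

warn_absent_regions <- function(requested, present) {
  missing <- setdiff(requested, present)
  if (length(missing)) {
    warn(sprintf("requested region(s) absent from file: %s",
                 paste(missing, collapse = ", ")))
  }
}

#' Read a Google-style community mobility CSV
#'
#' Parses the long-format dialect with one row per region and date and six
#' `*_percent_change_from_baseline` columns (percentage points relative to a
#' per-weekday baseline; empty cells become `NA`).
#'
#' @param path Path to the CSV file.
#' @param regions Optional character vector of sub-region labels to keep
#'   (exact match after whitespace trimming, case-sensitive). Requested
#'   regions absent from the file produce a warning.
#' @return A tibble with columns `region`, `date`, and the six category
#'   columns named as in [mobility_categories()].
#' @export
read_google_csv <- function(path, regions = NULL) {
  raw <- read_csv_chr(path)
  needed <- c("country_region", "sub_region_1", "date", unname(google_category_cols))
  absent <- setdiff(needed, names(raw))
  if (length(absent)) {
    abort(sprintf("not a Google mobility file: missing column(s) %s",
                  paste(absent, collapse = ", ")))
  }
  out <- tibble(
    region = trimws(raw$sub_region_1),
    date = if (nrow(raw)) parse_date_col(raw$date, "date") else as.Date(character())
  )
  for (nm in names(google_category_cols)) {
    out[[nm]] <- parse_num_cell(raw[[google_category_cols[[nm]]]],
                                google_category_cols[[nm]])
  }
  if (!is.null(regions)) {
    warn_absent_regions(regions, unique(out$region))
    out <- filter(out, .data$region %in% regions)
  }
  if (anyDuplicated(out[c("region", "date")])) {
    abort("duplicate (region, date) rows in Google file")
  }
  arrange(out, .data$region, .data$date)
}

#' Write a Google-style community mobility CSV
#'
#' Inverse of [read_google_csv()]: missing values are written as empty cells
#' so a round trip reproduces values and missingness exactly.
#'
#' @param x Tibble as returned by [read_google_csv()].
#' @param path Output path.
#' @param country Value for the `country_region` column.
#' @return Invisibly, `path`.
#' @export
write_google_csv <- function(x, path, country = "Austria") {
  out <- tibble(country_region = country, sub_region_1 = x$region,
                date = format(x$date, "%Y-%m-%d"))
  for (nm in names(google_category_cols)) out[[google_category_cols[[nm]]]] <- x[[nm]]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an Apple-style mobility trends CSV
#'
#' Parses the wide-format dialect (`geo_type`, `region`,
#' `transportation_type`, then one column per ISO date) into a long tibble.
#' Values are baseline-indexed volumes with 100 meaning the baseline day.
#'
#' @inheritParams read_google_csv
#' @return A tibble with columns `region`, `transportation_type`, `date`,
#'   `value` (empty cells become `NA`).
#' @export
read_apple_csv <- function(path, regions = NULL) {
  raw <- read_csv_chr(path)
  absent <- setdiff(c("geo_type", "region", "transportation_type"), names(raw))
  if (length(absent)) {
    abort(sprintf("not an Apple mobility file: missing column(s) %s",
                  paste(absent, collapse = ", ")))
  }
  date_cols <- grep("^\\d{4}-\\d{2}-\\d{2}$", names(raw), value = TRUE)
  if (!length(date_cols)) abort("not an Apple mobility file: no date columns")
  raw$region <- trimws(raw$region)
  if (anyDuplicated(raw[c("region", "transportation_type")])) {
    abort("duplicate (region, transportation_type) rows in Apple file")
  }
  out <- tidyr::pivot_longer(raw, cols = all_of(date_cols),
                             names_to = "date", values_to = "value")
  out$value <- parse_num_cell(out$value, "value")
  out <- tibble(region = out$region,
                transportation_type = out$transportation_type,
                date = as.Date(out$date), value = out$value)
  if (!is.null(regions)) {
    warn_absent_regions(regions, unique(out$region))
    out <- filter(out, .data$region %in% regions)
  }
  arrange(out, .data$region, .data$transportation_type, .data$date)
}

#' Write an Apple-style mobility trends CSV
#'
#' @param x Long tibble as returned by [read_apple_csv()].
#' @param path Output path.
#' @param geo_type Value for the `geo_type` column.
#' @return Invisibly, `path`.
#' @export
write_apple_csv <- function(x, path, geo_type = "city") {
  wide <- tidyr::pivot_wider(
    mutate(x, date = format(.data$date, "%Y-%m-%d")),
    names_from = "date", values_from = "value")
  wide <- arrange(wide, .data$region, .data$transportation_type)
  out <- dplyr::bind_cols(tibble(geo_type = geo_type), wide)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a daily outpatient count CSV
#'
#' Expects columns `city,date,sex,count` with `sex` in `female`/`male` and
#' nonnegative integer counts. The result is completed over the global date
#' span of the file, so a (city, date) pair with no row appears with `NA`
#' counts — these are the gaps the imputation stage fills.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `city`, `date`, `sex`, `count`, one row per
#'   city x date x sex over the global span.
#' @export
read_outpatients_csv <- function(path) {
  raw <- read_csv_chr(path)
  absent <- setdiff(c("city", "date", "sex", "count"), names(raw))
  if (length(absent)) {
    abort(sprintf("not an outpatient count file: missing column(s) %s",
                  paste(absent, collapse = ", ")))
  }
  if (!nrow(raw)) {
    return(tibble(city = character(), date = as.Date(character()),
                  sex = character(), count = integer()))
  }
  bad_sex <- setdiff(unique(raw$sex), c("female", "male"))
  if (length(bad_sex)) {
    abort(sprintf("invalid sex value(s): %s", paste(bad_sex, collapse = ", ")))
  }
  count <- parse_num_cell(raw$count, "count")
  if (any(count < 0, na.rm = TRUE)) {
    abort(sprintf("negative count at data row %d", which(count < 0)[1]))
  }
  if (any(count != round(count), na.rm = TRUE)) {
    abort(sprintf("non-integer count at data row %d", which(count != round(count))[1]))
  }
  x <- tibble(city = trimws(raw$city), date = parse_date_col(raw$date, "date"),
              sex = raw$sex, count = as.integer(round(count)))
  if (anyDuplicated(x[c("city", "date", "sex")])) {
    abort("duplicate (city, date, sex) rows in outpatient file")
  }
  span <- seq(min(x$date), max(x$date), by = "day")
  grid <- tidyr::expand_grid(city = sort(unique(x$city)), date = span,
                             sex = c("female", "male"))
  out <- left_join(grid, x, by = c("city", "date", "sex"))
  arrange(out, .data$city, .data$date, .data$sex)
}

#' Write a daily outpatient count CSV
#'
#' Gap rows (`NA` counts) are dropped on writing, so re-reading reproduces
#' the same observed values and the same gaps.
#'
#' @param x Tibble as returned by [read_outpatients_csv()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_outpatients_csv <- function(x, path) {
  out <- filter(x, !is.na(.data$count))
  out <- mutate(out, date = format(.data$date, "%Y-%m-%d"))
  readr::write_csv(out[c("city", "date", "sex", "count")], path, na = "")
  invisible(path)
}

#' Daily totals from a sex-stratified outpatient table
#'
#' @param x Tibble with columns `city`, `date`, `sex`, `count`.
#' @return A tibble `city`, `date`, `value` where `value` is female + male
#'   (`NA` when either stratum is missing).
#' @export
outpatient_totals <- function(x) {
  out <- summarise(group_by(x, .data$city, .data$date),
                   value = sum(.data$count), .groups = "drop")
  arrange(out, .data$city, .data$date)
}
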