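# Seeded generator for synthetic study data: daily trauma outpatient counts
# per city and sex, plus Google-style and Apple-style mobility files with
# correlated lockdown dips. The generator defines the study conditions the
# package is validated under: three cities at realistic admission rates,
# three lockdowns whose suppression attenuates over time (compliance
# decay), overdispersed counts, weekday seasonality, sporadic missing days,
# and a shared latent day effect that couples mobility to admissions so the
# mobility-index / outpatient-index correlation can be targeted.

# Relative weight of each Google category in the lockdown dip. Scaled so
# the leisure mobility index dips by exactly -100 * mobility_drop:
# (1.2 + 1.0 + 1.4 - (-0.4)) / 4 = 1.
synthetic_category_weights <- c(
  retail_recreation = 1.2, grocery_pharmacy = 0.6, parks = 1.0,
  transit = 1.4, workplaces = 1.0, residential = -0.4
)

# Apple direction-request volumes dip deeper than the composite index
# (driving reached about -75% when the index was near -47%).
synthetic_apple_weights <- c(driving = 1.6, walking = 1.5, transit = 1.7)

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the scale of the study setting: three cities observed
#' 2019-01-01 to 2021-02-08 with base rates near the observed 2019 daily
#' averages, three hard lockdowns with admission suppression fading across
#' lockdowns (compliance decay), negative-binomial daily counts, and a
#' target correlation of 0.7 between the leisure mobility index and the
#' outpatient index over the Google-era window.
#'
#' @param seed Integer seed; fully determines the output.
#' @param cities Named numeric vector of base mean outpatients/day per city.
#' @param start,end Span of the generated daily series (inclusive).
#' @param weekday_profile Seven multiplicative factors (Mon..Sun, mean 1)
#'   for admission weekday seasonality.
#' @param lockdowns Tibble with columns `name`, `start`, `end`,
#'   `mobility_drop`, `admission_drop` (drops as fractions in \[0, 1\]).
#' @param compliance_decay Attenuation factor >= 1 dividing the drops of
#'   the k-th lockdown by `compliance_decay^(k-1)`; the default of 1 leaves
#'   the per-lockdown drops (which already fade) as given.
#' @param dispersion Negative-binomial size parameter for daily counts
#'   (smaller = more overdispersed; variance is `mu + mu^2 / size`).
#' @param female_share Expected share of female outpatients per day.
#' @param latent_sd Standard deviation, in percentage points, of the shared
#'   latent day effect entering both the mobility index and the count mean.
#' @param target_corr Intended correlation between the mobility index and
#'   the outpatient index; the category noise level is solved from it
#'   unless `category_noise_sd` is given.
#' @param category_noise_sd Optional fixed per-category mobility noise SD
#'   (percentage points); `NULL` (default) calibrates it from
#'   `target_corr`.
#' @param missing_days Named integer vector of gap days per city in the
#'   count series.
#' @param mobility_missing_days Gap days per region in each mobility feed.
#' @param google_start First date of the Google-style feed (the provider
#'   began publishing in mid-February 2020).
#' @param apple_start First date of the Apple-style feed.
#' @param apple_baseline_date Baseline day of the Apple-style feed (value
#'   100 by construction).
#' @param aoi_reference_window 2019 window whose per-weekday medians define
#'   the outpatient baseline (mirror of the Google baseline window one year
#'   earlier); used by the noise calibration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             cities = c(Graz = 150, Innsbruck = 115, Vienna = 175),
                             start = "2019-01-01", end = "2021-02-08",
                             weekday_profile = c(1.05, 0.97, 0.95, 0.95, 1.00, 1.06, 1.02),
                             lockdowns = NULL,
                             compliance_decay = 1,
                             dispersion = 60,
                             female_share = 0.47,
                             latent_sd = 4,
                             target_corr = 0.7,
                             category_noise_sd = NULL,
                             missing_days = c(Graz = 38, Innsbruck = 30, Vienna = 0),
                             mobility_missing_days = 5L,
                             google_start = "2020-02-15",
                             apple_start = "2020-01-13",
                             apple_baseline_date = "2020-01-13",
                             aoi_reference_window = c("2019-01-03", "2019-02-06")) {
  if (is.null(lockdowns)) {
    lockdowns <- tibble(
      name = c("first", "second", "third"),
      start = as.Date(c("2020-03-16", "2020-11-17", "2020-12-26")),
      end = as.Date(c("2020-04-30", "2020-12-06", "2021-02-07")),
      mobility_drop = c(0.47, 0.36, 0.34),
      admission_drop = c(0.62, 0.40, 0.27))
  }
  stopifnot(length(weekday_profile) == 7, all(weekday_profile > 0),
            all(lockdowns$mobility_drop >= 0 & lockdowns$mobility_drop <= 1),
            all(lockdowns$admission_drop >= 0 & lockdowns$admission_drop <= 1),
            compliance_decay >= 1, dispersion > 0,
            female_share > 0, female_share < 1,
            !is.null(names(cities)), all(cities > 0))
  missing_days <- missing_days[names(cities)]
  missing_days[is.na(missing_days)] <- 0L
  names(missing_days) <- names(cities)
  structure(list(
    seed = as.integer(seed), cities = cities,
    start = as_iso_date(start), end = as_iso_date(end),
    weekday_profile = weekday_profile / mean(weekday_profile),
    lockdowns = mutate(lockdowns, start = as_iso_date(start), end = as_iso_date(end)),
    compliance_decay = compliance_decay, dispersion = dispersion,
    female_share = female_share, latent_sd = latent_sd,
    target_corr = target_corr, category_noise_sd = category_noise_sd,
    missing_days = setNames(as.integer(missing_days), names(cities)),
    mobility_missing_days = as.integer(mobility_missing_days),
    google_start = as_iso_date(google_start),
    apple_start = as_iso_date(apple_start),
    apple_baseline_date = as_iso_date(apple_baseline_date),
    aoi_reference_window = as_iso_date(aoi_reference_window)
  ), class = "synthetic_config")
}

# Effective drop (fraction) per date for one drop column, with compliance
# decay applied to successive lockdowns.
drop_profile <- function(dates, config, which = c("admission", "mobility")) {
  which <- match.arg(which)
  col <- paste0(which, "_drop")
  out <- numeric(length(dates))
  for (k in seq_len(nrow(config$lockdowns))) {
    eff <- min(1, config$lockdowns[[col]][k] / config$compliance_decay^(k - 1))
    inside <- dates >= config$lockdowns$start[k] & dates <= config$lockdowns$end[k]
    out[inside] <- eff
  }
  out
}

# Shared latent day effects (one standard-normal draw per city and day),
# derived from the seed alone so the count and mobility generators couple
# without sharing state.
latent_effects <- function(config) {
  days <- seq(config$start, config$end, by = "day")
  set.seed(config$seed)
  z <- matrix(rnorm(length(days) * length(config$cities)),
              nrow = length(days), ncol = length(config$cities),
              dimnames = list(NULL, names(config$cities)))
  list(days = days, z = z)
}

# Solve the per-category mobility noise SD so that the correlation between
# the mobility index and the outpatient index over the Google-era window
# targets `target_corr`. All variance components are computed analytically
# from the configured profiles: structural lockdown dips (shared by both
# series), the latent day effect, negative-binomial count noise, and the
# sampling error of the per-weekday median baseline.
calibrate_category_noise <- function(config) {
  days <- seq(config$google_start, config$end, by = "day")
  wk <- config$weekday_profile[weekday_index(days)]
  mob <- -100 * drop_profile(days, config, "mobility")
  adm <- drop_profile(days, config, "admission")
  aoi_struct <- -100 * adm
  one_m <- 1 - adm
  L <- config$latent_sd
  v_mi_struct <- var(mob)
  cov_tot <- cov(mob, aoi_struct) + L^2 * mean(one_m)
  v_mi_lat <- L^2

  # AOI baseline window (2019): per-weekday median of ~5 draws
  bw <- seq(config$aoi_reference_window[1], config$aoi_reference_window[2], by = "day")
  n_per_wd <- max(1, floor(length(bw) / 7))
  c_med <- pi / (2 * n_per_wd)

  r_t <- min(max(config$target_corr, 0.02), 0.98)
  sds <- vapply(names(config$cities), function(ct) {
    base <- config$cities[[ct]]
    mu <- base * wk * one_m
    v_aoi_nb <- mean((100 * one_m)^2 * (1 / mu + 1 / config$dispersion))
    mu_base <- base * mean(config$weekday_profile[weekday_index(bw)])
    v_base <- mean((100 * one_m)^2) * c_med * (1 / mu_base + 1 / config$dispersion)
    v_aoi_tot <- var(aoi_struct) + L^2 * mean(one_m^2) + v_aoi_nb + v_base
    v_mi_needed <- (cov_tot / (r_t * sqrt(v_aoi_tot)))^2 - v_mi_struct - v_mi_lat
    # four equally-weighted category noise terms -> MI noise var = sd^2 / 4
    2 * sqrt(max(v_mi_needed, 1))
  }, numeric(1))
  sds
}

#' Generate synthetic daily outpatient counts
#'
#' Draws one negative-binomial total per city and day with mean
#' `base * weekday factor * (1 - effective admission drop) * (1 + latent)`,
#' splits it binomially into female and male, and blanks the configured
#' number of seeded random gap days per city.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `city`, `date`, `sex`, `count` (`NA` on
#'   gap days).
#' @export
generate_outpatients <- function(config) {
  lat <- latent_effects(config)
  days <- lat$days
  wk <- config$weekday_profile[weekday_index(days)]
  adm <- drop_profile(days, config, "admission")
  set.seed(config$seed + 1L)
  out <- vector("list", length(config$cities))
  for (i in seq_along(config$cities)) {
    ct <- names(config$cities)[i]
    mu <- config$cities[[i]] * wk * (1 - adm) *
      pmax(0.05, 1 + config$latent_sd * lat$z[, ct] / 100)
    total <- rnbinom(length(days), mu = mu, size = config$dispersion)
    female <- rbinom(length(days), total, config$female_share)
    male <- total - female
    if (config$missing_days[[ct]] > 0) {
      gap <- sample(seq_along(days), config$missing_days[[ct]])
      female[gap] <- NA_integer_
      male[gap] <- NA_integer_
    }
    out[[i]] <- tibble(city = ct, date = rep(days, 2),
                       sex = rep(c("female", "male"), each = length(days)),
                       count = as.integer(c(female, male)))
  }
  arrange(bind_rows(out), .data$city, .data$date, .data$sex)
}

#' Generate synthetic Google-style and Apple-style mobility tables
#'
#' Each Google category follows the lockdown dip profile scaled by its
#' category weight (residential with opposite sign), plus the shared latent
#' day effect and independent noise whose SD is calibrated from
#' `target_corr` (see [synthetic_config()]). Apple-style volumes are the
#' same signal scaled deeper, written 100-indexed with the baseline day
#' fixed at exactly 100.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `google` (as [read_google_csv()] returns)
#'   and `apple` (as [read_apple_csv()] returns).
#' @export
generate_mobility <- function(config) {
  lat <- latent_effects(config)
  sds <- if (is.null(config$category_noise_sd)) {
    calibrate_category_noise(config)
  } else {
    setNames(rep(config$category_noise_sd, length(config$cities)),
             names(config$cities))
  }
  g_days <- seq(config$google_start, config$end, by = "day")
  a_days <- seq(config$apple_start, config$end, by = "day")
  g_idx <- match(g_days, lat$days)
  a_idx <- match(a_days, lat$days)
  set.seed(config$seed + 2L)
  google <- vector("list", length(config$cities))
  apple <- vector("list", length(config$cities))
  for (i in seq_along(config$cities)) {
    ct <- names(config$cities)[i]
    sig_g <- -100 * drop_profile(g_days, config, "mobility") +
      config$latent_sd * lat$z[g_idx, ct]
    gtab <- tibble(region = ct, date = g_days)
    for (cat in names(synthetic_category_weights)) {
      gtab[[cat]] <- synthetic_category_weights[[cat]] * sig_g +
        sds[[ct]] * rnorm(length(g_days))
    }
    if (config$mobility_missing_days > 0) {
      gap <- sample(seq_along(g_days), config$mobility_missing_days)
      gtab[gap, names(synthetic_category_weights)] <- NA_real_
    }
    google[[i]] <- gtab

    sig_a <- -100 * drop_profile(a_days, config, "mobility") +
      config$latent_sd * lat$z[a_idx, ct]
    b <- match(config$apple_baseline_date, a_days)
    atab <- vector("list", length(synthetic_apple_weights))
    for (j in seq_along(synthetic_apple_weights)) {
      tp <- names(synthetic_apple_weights)[j]
      v <- 100 + synthetic_apple_weights[[j]] * sig_a + sds[[ct]] * rnorm(length(a_days))
      v <- pmax(v, 1)
      v[b] <- 100  # baseline day is exact by construction of the format
      atab[[j]] <- tibble(region = ct, transportation_type = tp,
                          date = a_days, value = v)
    }
    atab <- bind_rows(atab)
    if (config$mobility_missing_days > 0) {
      pool <- setdiff(seq_along(a_days), b)
      gap <- a_days[sample(pool, config$mobility_missing_days)]
      atab$value[atab$date %in% gap] <- NA_real_
    }
    apple[[i]] <- atab
  }
  list(google = arrange(bind_rows(google), .data$region, .data$date),
       apple = arrange(bind_rows(apple), .data$region,
                       .data$transportation_type, .data$date))
}

#' Generate and write a complete synthetic dataset
#'
#' Runs both generators under the config seed and writes the three CSV
#' dialects (`google.csv`, `apple.csv`, `outpatients.csv`) to a directory.
#' The same seed produces byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return A list with elements `counts`, `google`, `apple`, and `paths`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  counts <- generate_outpatients(config)
  mob <- generate_mobility(config)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(google = file.path(dir, "google.csv"),
                  apple = file.path(dir, "apple.csv"),
                  outpatients = file.path(dir, "outpatients.csv"))
    write_google_csv(mob$google, paths$google)
    write_apple_csv(mob$apple, paths$apple)
    write_outpatients_csv(counts, paths$outpatients)
  }
  list(counts = counts, google = mob$google, apple = mob$apple, paths = paths)
}
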