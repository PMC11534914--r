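# One-command orchestration: read (files or synthetic) -> impute -> indices
# -> inference -> report. Stage errors abort with the stage name; outputs
# are only written once every stage has succeeded.

#' Pipeline configuration
#'
#' Exactly one input mode must be used: either all three file paths
#' (`google`, `apple`, `outpatients`) or a `synthetic` config.
#'
#' @param google,apple,outpatients Paths to the three input CSVs.
#' @param synthetic A [synthetic_config()] for file-free synthetic mode.
#' @param cities Optional character vector restricting the analysis; by
#'   default all cities present in the count data (mobility region labels
#'   are matched to city names exactly).
#' @param aoi_reference_window 2019 window whose per-weekday medians form
#'   the outpatient baseline (mirror, one year earlier, of the provider's
#'   2020-01-03..2020-02-06 baseline window).
#' @param apple_baseline_date Reference day for the single-day outpatient
#'   baseline matching the Apple convention.
#' @param lockdown_preset Passed to [lockdown_periods()].
#' @param impute Fill gaps by [impute_seasonal_split()] before index
#'   computation (the default); with `FALSE`, incomplete dates are dropped
#'   pairwise in the inference stage.
#' @param pooling `"pairs"` pools the daily pairs of all cities into one
#'   sample for the "All cities" row; `"average_indices"` instead averages
#'   the two indices across cities per date and correlates the averages.
#' @param alpha Significance level for intervals and flags.
#' @param out_dir Optional directory; when given, tables, series and a run
#'   log are written there after all stages succeed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(google = NULL, apple = NULL, outpatients = NULL,
                            synthetic = NULL, cities = NULL,
                            aoi_reference_window = c("2019-01-03", "2019-02-06"),
                            apple_baseline_date = "2020-01-13",
                            lockdown_preset = "published",
                            impute = TRUE,
                            pooling = c("pairs", "average_indices"),
                            alpha = 0.05, out_dir = NULL) {
  file_mode <- !is.null(google) || !is.null(apple) || !is.null(outpatients)
  if (file_mode && !is.null(synthetic)) {
    abort("give either input file paths or `synthetic`, not both")
  }
  if (file_mode && (is.null(google) || is.null(apple) || is.null(outpatients))) {
    abort("file mode needs all three paths: `google`, `apple`, `outpatients`")
  }
  if (!file_mode && is.null(synthetic)) {
    abort("no input: give the three file paths or a `synthetic` config")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    abort("`synthetic` must be a synthetic_config()")
  }
  structure(list(
    mode = if (file_mode) "files" else "synthetic",
    google = google, apple = apple, outpatients = outpatients,
    synthetic = synthetic, cities = cities,
    aoi_reference_window = as_iso_date(aoi_reference_window),
    apple_baseline_date = as_iso_date(apple_baseline_date),
    lockdown_preset = lockdown_preset, impute = isTRUE(impute),
    pooling = match.arg(pooling), alpha = alpha, out_dir = out_dir
  ), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

impute_by_group <- function(df, group_cols, log) {
  keys <- distinct(df[group_cols])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df
    for (gc in group_cols) sub <- filter(sub, .data[[gc]] == keys[[gc]][i])
    imp <- impute_seasonal_split(sub[c("date", "value")])
    log[[paste(unlist(keys[i, ]), collapse = "/")]] <- attr(imp, "n_imputed")
    for (gc in group_cols) imp[[gc]] <- keys[[gc]][i]
    out[[i]] <- imp
  }
  list(data = bind_rows(out), log = log)
}

#' Run the full mobility-vs-admissions pipeline
#'
#' Fixed stage order: read (or simulate), impute raw inputs, compute
#' indices (leisure mobility index and both outpatient index conventions),
#' run per-city and pooled inference for both providers, and assemble the
#' report tables and weekly series. Any stage error aborts with the stage
#' name; with `out_dir` set, nothing is written unless every stage
#' succeeded.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `tables` (correlation and lockdown tables),
#'   `indices`, `weekly`, `inference` (per-city/pooled correlation and
#'   regression results), and `log` (sample sizes, imputed-day counts per
#'   series, config hash).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  run_stage("validate", {
    if (config$mode == "files") {
      for (p in c(config$google, config$apple, config$outpatients)) {
        if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
      }
    }
  })

  inputs <- run_stage("read", {
    if (config$mode == "files") {
      list(google = read_google_csv(config$google, regions = config$cities),
           apple = read_apple_csv(config$apple, regions = config$cities),
           counts = read_outpatients_csv(config$outpatients))
    } else {
      sim <- simulate_dataset(config$synthetic)
      list(google = sim$google, apple = sim$apple, counts = sim$counts)
    }
  })
  counts <- inputs$counts
  if (!is.null(config$cities)) counts <- filter(counts, .data$city %in% config$cities)
  cities <- sort(unique(counts$city))

  imputed_log <- list()
  imputed <- run_stage("impute", {
    if (!config$impute) {
      list(google = inputs$google, apple = inputs$apple, counts = counts,
           log = list())
    } else {
      log <- list()
      cl <- rename(counts, value = "count")
      res <- impute_by_group(cl, c("city", "sex"), log)
      counts_i <- rename(res$data, count = "value")[names(counts)]
      log <- res$log
      google_i <- inputs$google
      for (cat in mobility_categories()) {
        gl <- rename(inputs$google, value = all_of(cat))[c("region", "date", "value")]
        res <- impute_by_group(gl, "region", list())
        m <- match(paste(google_i$region, google_i$date),
                   paste(res$data$region, res$data$date))
        google_i[[cat]] <- res$data$value[m]
        for (nm in names(res$log)) {
          log[[paste0("google/", nm, "/", cat)]] <- res$log[[nm]]
        }
      }
      al <- inputs$apple
      res <- impute_by_group(al, c("region", "transportation_type"), list())
      for (nm in names(res$log)) log[[paste0("apple/", nm)]] <- res$log[[nm]]
      list(google = google_i, apple = res$data[names(inputs$apple)],
           counts = counts_i, log = log)
    }
  })
  imputed_log <- imputed$log

  idx <- run_stage("indices", {
    totals <- outpatient_totals(imputed$counts)
    mi <- mobility_index(imputed$google)
    acfb <- apple_cfb(imputed$apple)
    aoi_g <- list(); aoi_a <- list()
    for (ct in cities) {
      tot_ct <- filter(totals, .data$city == ct)[c("date", "value")]
      bl <- weekday_median_baseline(tot_ct, config$aoi_reference_window)
      aoi_g[[ct]] <- aoi_google(tot_ct, bl)
      aoi_a[[ct]] <- aoi_apple(tot_ct, config$apple_baseline_date)
    }
    list(totals = totals, mi = mi, apple_cfb = acfb,
         aoi_google = aoi_g, aoi_apple = aoi_a)
  })

  inf <- run_stage("inference", {
    pair_up <- function(mob_tbl, aoi_list) {
      lapply(setNames(cities, cities), function(ct) {
        m <- filter(mob_tbl, .data$region == ct)
        a <- aoi_list[[ct]]
        d <- left_join(m[c("date", "value")], a, by = "date",
                       suffix = c("_x", "_y"))
        tibble(date = d$date, x = d$value_x, y = d$value_y)
      })
    }
    one_provider <- function(mob_tbl, aoi_list) {
      pairs <- pair_up(mob_tbl, aoi_list)
      per_city_corr <- lapply(pairs, function(d) pearson_corr(d$x, d$y, config$alpha))
      per_city_ols <- lapply(pairs, function(d) simple_ols(d$x, d$y))
      pooled_d <- if (config$pooling == "pairs") {
        pooled_pairs(pairs)
      } else {
        avg <- summarise(group_by(bind_rows(pairs), .data$date),
                         x = mean(.data$x), y = mean(.data$y), .groups = "drop")
        filter(avg[c("x", "y")], !is.na(.data$x), !is.na(.data$y))
      }
      list(per_city_corr = per_city_corr, per_city_ols = per_city_ols,
           pooled_corr = pearson_corr(pooled_d$x, pooled_d$y, config$alpha),
           pooled_ols = simple_ols(pooled_d$x, pooled_d$y))
    }
    list(google = one_provider(idx$mi, idx$aoi_google),
         apple = one_provider(idx$apple_cfb, idx$aoi_apple))
  })

  report <- run_stage("report", {
    corr_tbl <- bind_rows(
      correlation_table(inf$google$per_city_corr, inf$google$pooled_corr, "Google"),
      correlation_table(inf$apple$per_city_corr, inf$apple$pooled_corr, "Apple"))
    periods <- lockdown_periods(config$lockdown_preset)
    ld_tbl <- lockdown_table(imputed$counts, periods)
    weekly_counts <- bind_rows(lapply(setNames(cities, cities), function(ct) {
      weekly_mean(filter(idx$totals, .data$city == ct)[c("date", "value")])
    }), .id = "city")
    weekly_mi <- bind_rows(lapply(setNames(cities, cities), function(ct) {
      weekly_mean(filter(idx$mi, .data$region == ct)[c("date", "value")])
    }), .id = "city")
    list(correlation = corr_tbl, correlation_formatted = format_correlation_table(corr_tbl),
         lockdown = ld_tbl, weekly_counts = weekly_counts, weekly_mi = weekly_mi)
  })

  log <- list(
    config_hash = rlang::hash(unclass(config)),
    alpha = config$alpha, cities = cities,
    n_pairs = lapply(inf, function(pr) {
      c(vapply(pr$per_city_corr, function(x) x$n, numeric(1)),
        `All cities` = pr$pooled_corr$n)
    }),
    imputed_days = imputed_log)

  bundle <- list(tables = report[c("correlation", "correlation_formatted", "lockdown")],
                 indices = idx, weekly = report[c("weekly_counts", "weekly_mi")],
                 inference = inf, log = log)

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      d <- config$out_dir
      if (!dir.exists(d)) dir.create(d, recursive = TRUE)
      readr::write_csv(report$correlation, file.path(d, "correlation_table.csv"))
      readr::write_csv(report$correlation_formatted,
                       file.path(d, "correlation_table_formatted.csv"))
      readr::write_csv(report$lockdown, file.path(d, "lockdown_table.csv"))
      readr::write_csv(report$weekly_counts, file.path(d, "weekly_outpatients.csv"))
      readr::write_csv(report$weekly_mi, file.path(d, "weekly_mobility_index.csv"))
      log_lines <- c(
        sprintf("config_hash: %s", log$config_hash),
        sprintf("alpha: %g", log$alpha),
        sprintf("n_pairs_google: %s",
                paste(names(log$n_pairs$google), log$n_pairs$google,
                      sep = "=", collapse = ", ")),
        sprintf("n_pairs_apple: %s",
                paste(names(log$n_pairs$apple), log$n_pairs$apple,
                      sep = "=", collapse = ", ")),
        sprintf("imputed_days: %s",
                paste(names(log$imputed_days), unlist(log$imputed_days),
                      sep = "=", collapse = ", ")))
      writeLines(log_lines, file.path(d, "log.txt"))
    })
  }
  bundle
}
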