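small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, cities = c(Graz = 120, Vienna = 150),
                   missing_days = c(Graz = 3, Vienna = 0),
                   mobility_missing_days = 2, ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  simulate_dataset(small_config(seed = 42), dir = d1)
  simulate_dataset(small_config(seed = 42), dir = d2)
  for (f in c("google.csv", "apple.csv", "outpatients.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes the data
  d3 <- tempfile("sim3")
  simulate_dataset(small_config(seed = 43), dir = d3)
  expect_false(identical(readLines(file.path(d1, "outpatients.csv")),
                         readLines(file.path(d3, "outpatients.csv"))))
})

test_that("counts follow the configured structure", {
  cfg <- small_config(seed = 2)
  counts <- generate_outpatients(cfg)
  expect_setequal(unique(counts$city), c("Graz", "Vienna"))
  expect_equal(sum(is.na(counts$count[counts$city == "Graz"])), 2 * 3)
  expect_equal(sum(is.na(counts$count[counts$city == "Vienna"])), 0)
  expect_true(all(counts$count >= 0, na.rm = TRUE))
  # overall level near the configured base rates outside lockdowns
  tot <- outpatient_totals(counts)
  pre <- tot[tot$date < as.Date("2020-03-01") & tot$city == "Vienna", ]
  expect_lt(abs(mean(pre$value, na.rm = TRUE) - 150), 5)
})

test_that("zero admission drop leaves no systematic lockdown dip", {
  cfg <- synthetic_config(seed = 3, cities = c(Vienna = 150),
                          missing_days = c(Vienna = 0))
  cfg$lockdowns$admission_drop[] <- 0
  counts <- outpatient_totals(generate_outpatients(cfg))
  l1 <- cfg$lockdowns[1, ]
  during <- counts$value[counts$date >= l1$start & counts$date <= l1$end]
  before <- counts$value[counts$date < l1$start]
  se <- sqrt(var(during) / length(during) + var(before) / length(before))
  expect_lt(abs(mean(during) - mean(before)), 3 * se)
})

test_that("the injected first-lockdown admission drop reappears in the summary table", {
  cfg <- synthetic_config(seed = 4)  # defaults: drops 0.62 / 0.40 / 0.27
  counts <- generate_outpatients(cfg)
  # impute the gaps as the pipeline would before summarising
  imp <- dplyr::bind_rows(lapply(split(counts, paste(counts$city, counts$sex)), function(s) {
    out <- impute_seasonal_split(dplyr::rename(s, value = "count"))
    out$city <- s$city[1]; out$sex <- s$sex[1]
    dplyr::rename(out, count = "value")
  }))
  tbl <- lockdown_table(imp, lockdown_periods("published"))
  first_total <- tbl$diff_pct[tbl$period == "first" & tbl$sex == "total"]
  expect_lt(abs(mean(first_total) - (-62)), 2)
})

test_that("noiseless, uncoupled mobility equals the deterministic dip profile", {
  cfg <- small_config(seed = 5, latent_sd = 0, category_noise_sd = 0,
                      target_corr = 0.7)
  cfg$mobility_missing_days <- 0L
  mob <- generate_mobility(cfg)
  mi <- mobility_index(mob$google)
  vie <- mi[mi$region == "Vienna", ]
  l1 <- cfg$lockdowns[1, ]
  expect_equal(unique(vie$value[vie$date >= l1$start & vie$date <= l1$end]),
               -100 * l1$mobility_drop)
  expect_equal(unique(vie$value[vie$date < l1$start]), 0)
})

test_that("compliance decay attenuates the drops of successive lockdowns", {
  cfg <- small_config(seed = 6, compliance_decay = 2)
  days <- seq(cfg$start, cfg$end, by = "day")
  adm <- mobadmit:::drop_profile(days, cfg, "admission")
  in_l <- function(k) days >= cfg$lockdowns$start[k] & days <= cfg$lockdowns$end[k]
  expect_equal(unique(adm[in_l(1)]), 0.62)
  expect_equal(unique(adm[in_l(2)]), 0.40 / 2)
  expect_equal(unique(adm[in_l(3)]), 0.27 / 4)
})

test_that("Apple-style output is 100-indexed with an exact baseline day", {
  cfg <- small_config(seed = 8)
  ap <- generate_mobility(cfg)$apple
  expect_true(all(ap$value >= 0, na.rm = TRUE))
  at_baseline <- ap$value[ap$date == cfg$apple_baseline_date]
  expect_true(all(at_baseline == 100))
  expect_setequal(unique(ap$transportation_type), c("driving", "walking", "transit"))
})

test_that("the mobility-admissions coupling approaches the target correlation", {
  est_r <- function(seed, target) {
    cfg <- synthetic_config(seed = seed, cities = c(Vienna = 175),
                            missing_days = c(Vienna = 0),
                            mobility_missing_days = 0, target_corr = target)
    tot <- outpatient_totals(generate_outpatients(cfg))[c("date", "value")]
    tot <- impute_seasonal_split(tot)
    mi <- mobility_index(generate_mobility(cfg)$google)
    bl <- weekday_median_baseline(tot, cfg$aoi_reference_window)
    aoi <- aoi_google(tot, bl)
    d <- dplyr::left_join(mi[c("date", "value")], aoi, by = "date",
                          suffix = c("_x", "_y"))
    pearson_corr(d$value_x, d$value_y)$r
  }
  rs <- vapply(1:5, est_r, numeric(1), target = 0.7)
  expect_true(all(rs > 0.55 & rs < 0.85))
  r0 <- est_r(1, target = 0.02)
  expect_lt(abs(r0), 0.2)
})
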