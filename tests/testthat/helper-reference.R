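# Published three-city lockdown summary: average outpatients per day in
# each lockdown window and its previous-year reference, with the printed
# integer percent difference. Used to check that the reporting rounding
# convention recomputes the printed cells.
reference_lockdown_summary <- function() {
  tibble::tribble(
    ~city, ~sex, ~period, ~ao_d_ref, ~ao_d_cur, ~printed_diff,
    "Graz", "female", "first", 78.9, 28, -64,
    "Graz", "female", "second", 80.7, 60.8, -25,
    "Graz", "female", "third", 73.8, 56.8, -23,
    "Graz", "male", "first", 73.9, 26.9, -64,
    "Graz", "male", "second", 69.9, 53.9, -23,
    "Graz", "male", "third", 65.1, 37.7, -42,
    "Graz", "total", "first", 152.8, 54.9, -64,
    "Graz", "total", "second", 150.6, 114.6, -24,
    "Graz", "total", "third", 138.9, 94.5, -32,
    "Innsbruck", "female", "first", 50.3, 20, -60,
    "Innsbruck", "female", "second", 46.3, 26.7, -42,
    "Innsbruck", "female", "third", 54.7, 46.3, -15,
    "Innsbruck", "male", "first", 65.4, 24.7, -62,
    "Innsbruck", "male", "second", 59.4, 30.2, -49,
    "Innsbruck", "male", "third", 62.3, 50.1, -20,
    "Innsbruck", "total", "first", 115.7, 44.8, -61,
    "Innsbruck", "total", "second", 105.7, 56.8, -46,
    "Innsbruck", "total", "third", 117, 96.4, -18,
    "Vienna", "female", "first", 87.4, 33.1, -62,
    "Vienna", "female", "second", 84.5, 47.8, -43,
    "Vienna", "female", "third", 77, 55.4, -28,
    "Vienna", "male", "first", 101.1, 37.8, -63,
    "Vienna", "male", "second", 85.6, 47.5, -45,
    "Vienna", "male", "third", 80.9, 53.2, -34,
    "Vienna", "total", "first", 188.5, 70.9, -62,
    "Vienna", "total", "second", 170.1, 95.3, -44,
    "Vienna", "total", "third", 157.9, 108.6, -31
  )
}

# Agreement to `tol`, absolute near zero and relative away from it.
expect_agree <- function(a, b, tol = 1e-10) {
  testthat::expect_lt(abs(a - b), tol * max(1, abs(b)))
}

# Textbook product-moment / least-squares formulas, used as an independent
# brute-force oracle against the package's inference routines.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - my)^2)
  r2 <- 1 - sse / sst
  f <- (sst - sse) / (sse / (n - 2))
  list(intercept = intercept, slope = slope, r2 = r2, f_stat = f,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}
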