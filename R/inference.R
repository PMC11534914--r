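# Association between the mobility index and the outpatient index:
# Pearson correlation with Fisher-z interval and simple least-squares
# regression, per city and pooled. Estimation is delegated to the standard
# stats machinery (cor.test, lm); this module fixes the pairing, error
# handling and result contracts.

drop_incomplete_pairs <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation over complete pairs; two-sided p-value from
#' the t transform of r with n - 2 degrees of freedom, and a confidence
#' interval from the Fisher-z transform (see [fisher_ci()]).
#'
#' @param x,y Numeric vectors of equal length; dates missing in either are
#'   dropped pairwise.
#' @param alpha Significance level (default 0.05, i.e. a 95% interval).
#' @return A one-row tibble with columns `r`, `n`, `ci_low`, `ci_high`,
#'   `p`, `alpha`.
#' @export
pearson_corr <- function(x, y, alpha = 0.05) {
  p <- drop_incomplete_pairs(x, y)
  if (p$n < 3) abort("need at least 3 complete pairs")
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    abort("correlation undefined: zero variance in x or y")
  }
  ct <- cor.test(p$x, p$y, method = "pearson", conf.level = 1 - alpha)
  r <- unname(ct$estimate)
  if (p$n >= 4 && abs(r) < 1) {
    ci <- fisher_ci(r, p$n, alpha)
  } else {
    warn("confidence interval unavailable (n < 4 or |r| = 1)")
    ci <- c(NA_real_, NA_real_)
  }
  tibble(r = r, n = p$n, ci_low = ci[1], ci_high = ci[2],
         p = ct$p.value, alpha = alpha)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' Variance-stabilising interval: `z = artanh(r)` with standard error
#' `1 / sqrt(n - 3)`; the normal-quantile half-width is applied on the z
#' scale and back-transformed by `tanh`.
#'
#' @param r Correlation coefficient with `|r| < 1`.
#' @param n Number of pairs (at least 4).
#' @param alpha Significance level (default 0.05).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  if (abs(r) >= 1) abort("Fisher interval degenerate for |r| = 1")
  if (n < 4) abort("Fisher interval requires n >= 4")
  z <- atanh(r)
  hw <- qnorm(1 - alpha / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Simple least-squares regression of y on x
#'
#' Fits `y = intercept + slope * x` by ordinary least squares over complete
#' pairs and reports the usual single-predictor summaries: r-squared,
#' adjusted r-squared, the F statistic on (1, n - 2) degrees of freedom and
#' its p-value.
#'
#' @inheritParams pearson_corr
#' @return A one-row tibble with columns `intercept`, `slope`, `r2`,
#'   `adj_r2`, `f_stat`, `df1`, `df2`, `p`, `n`.
#' @export
simple_ols <- function(x, y) {
  p <- drop_incomplete_pairs(x, y)
  if (p$n < 3) abort("need at least 3 complete pairs")
  if (sd(p$x) == 0) abort("regression undefined: zero variance in x")
  fit <- lm(p$y ~ p$x)
  s <- summary(fit)
  f <- unname(s$fstatistic)
  n_pairs <- p$n
  tibble(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         r2 = s$r.squared, adj_r2 = s$adj.r.squared,
         f_stat = f[1], df1 = as.integer(f[2]), df2 = as.integer(f[3]),
         p = pf(f[1], f[2], f[3], lower.tail = FALSE), n = n_pairs)
}

#' Adjusted r-squared from a printed F statistic
#'
#' Recovers the coefficient of determination of a single-predictor fit from
#' its F statistic, `r2 = F * df1 / (F * df1 + df2)`, and adjusts it for
#' model size: `1 - (1 - r2) * (n - 1) / df2` with `n = df1 + df2 + 1`.
#' Useful for checking reported regression summaries analytically.
#'
#' @param f_stat Nonnegative F statistic.
#' @param df1 Numerator degrees of freedom (1 for simple regression).
#' @param df2 Denominator (residual) degrees of freedom, at least 2.
#' @return The adjusted r-squared.
#' @export
adj_r2_from_f <- function(f_stat, df1 = 1L, df2) {
  stopifnot(f_stat >= 0, df1 >= 1, df2 >= 2)
  r2 <- f_stat * df1 / (f_stat * df1 + df2)
  n <- df1 + df2 + 1
  1 - (1 - r2) * (n - 1) / df2
}

#' Pool per-city index pairs into one sample
#'
#' Concatenates the complete daily (x, y) pairs of several cities into a
#' single sample, the default construction behind an "all cities" row.
#'
#' @param per_city A list of tibbles, each with numeric columns `x` and `y`.
#' @return One tibble with columns `x`, `y` (complete pairs only).
#' @export
pooled_pairs <- function(per_city) {
  if (!length(per_city)) abort("need at least one city")
  out <- bind_rows(lapply(per_city, function(d) tibble(x = d$x, y = d$y)))
  filter(out, !is.na(.data$x), !is.na(.data$y))
}
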