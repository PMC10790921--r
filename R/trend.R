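# Trend-analysis suite: Mann-Kendall, Sen's slope, Durbin-Watson with
# Savin-White bounds, split-half reliability, and the publication-shaped
# trend report.

#' Mann-Kendall test for monotonic trend
#'
#' Nonparametric trend test on an ordered series:
#' \eqn{S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)} over all non-missing pairs,
#' with the tie-corrected null variance
#' \eqn{\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_p t_p(t_p-1)(2t_p+5)]/18}
#' and the continuity-corrected normal deviate
#' \eqn{Z = (S \mp 1)/\sqrt{\mathrm{var}(S)}}. The reported direction is the
#' sign of `S` when the two-sided p-value is below 0.05, otherwise `"none"`.
#'
#' @param series Ordered numeric values; `NA` allowed (pairs involving `NA`
#'   are dropped). At least 4 non-missing values required.
#' @return An object of class `cv_mk` with fields `S`, `var_S`, `se`, `Z`,
#'   `p_value`, `direction`, `n`.
#' @examples
#' mann_kendall(c(1, 2, 3, 5, 4, 6))
#' @export
mann_kendall <- function(series) {
  if (!is.numeric(series)) cv_abort("`series` must be numeric.", "bad_argument")
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 4) cv_abort("Need at least 4 non-missing values.", "bad_argument")
  d <- outer(x, x, "-")
  s_stat <- sum(sign(d[lower.tri(d)]))
  tie_sizes <- as.numeric(table(x))
  tie_sizes <- tie_sizes[tie_sizes > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  se <- sqrt(var_s)
  z <- if (s_stat > 0) (s_stat - 1) / se else if (s_stat < 0) (s_stat + 1) / se else 0
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (is.finite(p) && p < 0.05) {
    if (s_stat > 0) "positive" else "negative"
  } else "none"
  structure(
    list(S = s_stat, var_S = var_s, se = se, Z = z, p_value = p,
         direction = direction, n = n),
    class = "cv_mk"
  )
}

#' @export
print.cv_mk <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %g, se = %.3f, Z = %.3f, p = %.4g (%s), n = %d\n",
              x$S, x$se, x$Z, x$p_value, x$direction, x$n))
  invisible(x)
}

#' Sen's slope with rank-based confidence band
#'
#' The median of all pairwise slopes \eqn{(x_j - x_i)/(j - i)} (original
#' positions are used as abscissae, so missing values widen the spacing).
#' The confidence band uses the rank method: with
#' \eqn{C = z_{1-\alpha/2}\sqrt{\mathrm{var}(S)}} (tie-corrected Mann-Kendall
#' variance) and N pairwise slopes, the limits are the \eqn{M_1}-th smallest
#' and \eqn{(M_2+1)}-th smallest slope, \eqn{M_1 = (N - C)/2},
#' \eqn{M_2 = (N + C)/2} (ranks rounded to the nearest integer and clamped to
#' `[1, N]`).
#'
#' @param series Ordered numeric values; `NA` allowed; >= 4 non-missing.
#' @param conf_level Confidence level for the band (default 0.95).
#' @return An object of class `cv_sen`: `slope` (series units per position),
#'   `ci_lower`, `ci_upper`, `conf_level`, `n_pairs`.
#' @examples
#' sens_slope(c(3, 1, 2, 4, 6, 5))
#' @export
sens_slope <- function(series, conf_level = 0.95) {
  if (!is.numeric(series)) cv_abort("`series` must be numeric.", "bad_argument")
  check_number(conf_level, "conf_level", lower = 0.5, upper = 1 - 1e-9)
  keep <- !is.na(series)
  x <- series[keep]
  pos <- which(keep)
  n <- length(x)
  if (n < 4) cv_abort("Need at least 4 non-missing values.", "bad_argument")
  dv <- outer(x, x, "-")
  dp <- outer(pos, pos, "-")
  lt <- lower.tri(dv)
  slopes <- dv[lt] / dp[lt]
  slope <- stats::median(slopes)
  mk <- mann_kendall(series)
  cc <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(mk$var_S)
  nn <- length(slopes)
  ss <- sort(slopes)
  r1 <- min(nn, max(1L, round((nn - cc) / 2)))
  r2 <- min(nn, max(1L, round((nn + cc) / 2) + 1L))
  structure(
    list(slope = slope, ci_lower = ss[r1], ci_upper = ss[r2],
         conf_level = conf_level, n_pairs = nn),
    class = "cv_sen"
  )
}

#' @export
print.cv_sen <- function(x, ...) {
  cat(sprintf("Sen's slope: %.4g  [%.4g, %.4g] (%g%% CI, %d pairs)\n",
              x$slope, x$ci_lower, x$ci_upper, 100 * x$conf_level, x$n_pairs))
  invisible(x)
}

# Savin-White 5% significance bounds for the Durbin-Watson statistic, one
# regressor plus intercept. Tabulated n = 15..100 (selected rows; linear
# interpolation in between). Only the n = 30 row is used by the standard
# 30-bucket analysis; interpolated values at other n are approximate.
dw_table <- data.frame(
  n  = c(15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100),
  dl = c(1.077, 1.201, 1.288, 1.352, 1.402, 1.442, 1.475, 1.503, 1.528, 1.549,
         1.567, 1.583, 1.598, 1.611, 1.624, 1.635, 1.645, 1.654),
  du = c(1.361, 1.411, 1.454, 1.489, 1.519, 1.544, 1.566, 1.585, 1.601, 1.616,
         1.629, 1.641, 1.652, 1.662, 1.671, 1.679, 1.687, 1.694)
)

#' Durbin-Watson 5% bounds (one regressor)
#'
#' Lower and upper Savin-White critical bounds for the Durbin-Watson
#' statistic at the 5% level with a single regressor plus intercept;
#' linearly interpolated between tabulated sample sizes. `n` above 100 uses
#' the n = 100 row.
#'
#' @param n Number of observations (>= 15).
#' @return Named numeric vector `c(d_lower, d_upper)`.
#' @examples
#' dw_bounds(30)  # c(1.352, 1.489)
#' @export
dw_bounds <- function(n) {
  check_number(n, "n", integerish = TRUE)
  if (n < min(dw_table$n)) {
    cv_abort("Durbin-Watson bounds are tabulated for n >= 15.", "bad_argument")
  }
  n <- min(n, max(dw_table$n))
  c(d_lower = stats::approx(dw_table$n, dw_table$dl, n)$y,
    d_upper = stats::approx(dw_table$n, dw_table$du, n)$y)
}

# D = sum of squared successive residual differences over the residual sum of
# squares; in [0, 4], ~2 under independence.
dw_statistic <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Durbin-Watson autocorrelation diagnostic
#'
#' Fits an ordinary least-squares line on the observation index, computes the
#' first-order autocorrelation statistic
#' \eqn{D = \sum_{i \ge 2}(e_i - e_{i-1})^2 / \sum e_i^2} of the residuals,
#' and compares it with the Savin-White 5% bounds for one regressor. The
#' standard three-zone verdict is reported (`D < d_lower`: positive
#' autocorrelation; between the bounds: inconclusive; `D > d_upper`: none
#' detected) together with the binary `D < d_upper` rule
#' (`du_rule_significant`) used in the original validation analysis.
#'
#' @param series Ordered numeric values; `NA` allowed (positions kept as the
#'   regressor); >= 6 non-missing and non-degenerate residual variance.
#' @return An object of class `cv_dw`: `D`, `d_lower`, `d_upper`, `verdict`,
#'   `du_rule_significant`, `n`.
#' @export
durbin_watson <- function(series) {
  if (!is.numeric(series)) cv_abort("`series` must be numeric.", "bad_argument")
  keep <- !is.na(series)
  y <- series[keep]
  pos <- which(keep)
  n <- length(y)
  if (n < 6) cv_abort("Need at least 6 non-missing values.", "bad_argument")
  fit <- stats::lm.fit(cbind(1, pos), y)
  e <- fit$residuals
  if (sum(e^2) <= 1e-10 * max(1, sum((y - mean(y))^2))) {
    cv_abort("Residual variance is zero (perfect linear fit); D is undefined.",
             "degenerate")
  }
  d_val <- dw_statistic(e)
  bd <- dw_bounds(n)
  verdict <- if (d_val < bd[["d_lower"]]) {
    "positive_autocorrelation"
  } else if (d_val <= bd[["d_upper"]]) {
    "inconclusive"
  } else {
    "none_detected"
  }
  structure(
    list(D = d_val, d_lower = bd[["d_lower"]], d_upper = bd[["d_upper"]],
         verdict = verdict, du_rule_significant = d_val < bd[["d_upper"]],
         n = n),
    class = "cv_dw"
  )
}

#' @export
print.cv_dw <- function(x, ...) {
  cat(sprintf("Durbin-Watson: D = %.3f, bounds (%.3f, %.3f), %s\n",
              x$D, x$d_lower, x$d_upper, x$verdict))
  invisible(x)
}

#' Split-half reliability of the minute-level series
#'
#' Pearson correlation between the odd-timestamp and even-timestamp halves of
#' a 60-value minute-by-minute detection-percentage series (values paired by
#' rank order within each half).
#'
#' @param minute_series Numeric vector of 60 values (minutes in order), or
#'   the tibble from [minute_detection_series()]. No missing values allowed;
#'   both halves must have non-zero variance.
#' @return The correlation coefficient (numeric scalar).
#' @export
split_half_reliability <- function(minute_series) {
  if (is.data.frame(minute_series)) minute_series <- minute_series$perf
  if (!is.numeric(minute_series) || length(minute_series) != 60) {
    cv_abort("`minute_series` must hold 60 minute values.", "bad_argument")
  }
  if (anyNA(minute_series)) {
    cv_abort("`minute_series` must not contain missing values.", "bad_argument")
  }
  odd <- minute_series[seq(1, 59, by = 2)]
  even <- minute_series[seq(2, 60, by = 2)]
  if (stats::sd(odd) == 0 || stats::sd(even) == 0) {
    cv_abort("A zero-variance half makes the correlation undefined.", "degenerate")
  }
  stats::cor(odd, even)
}

#' Trend report over static and dynamic cohorts
#'
#' Runs the full analysis battery -- Durbin-Watson with bounds and both
#' verdict conventions, Mann-Kendall with continuity-corrected Z, and Sen's
#' slope with confidence band -- on the ensemble vigilance curves of the two
#' conditions, for the pooled total and each screen. Column order follows the
#' published layout: dynamic/static all screens, then left, center, right.
#'
#' Two-sided Mann-Kendall p-values are used throughout; the binary
#' `D < d_upper` autocorrelation rule is reported alongside the standard
#' three-zone verdict for comparability with the original analysis.
#'
#' @param static_curves,dynamic_curves A list of `cv_curve` objects (one per
#'   participant; the ensemble average is computed internally) or a single
#'   ensemble `cv_curve`.
#' @param conf_level Confidence level for the Sen's slope band.
#' @return A `cv_trend_report` tibble: 8 rows (`mode` x `screen`) and 13
#'   statistic columns. See [trend_report_table()] for the transposed
#'   publication layout.
#' @export
trend_report <- function(static_curves, dynamic_curves, conf_level = 0.95) {
  ens <- list(
    static = if (inherits(static_curves, "cv_curve") &&
                 any(grepl("_sd$", names(static_curves))))
      static_curves else ensemble_average(static_curves),
    dynamic = if (inherits(dynamic_curves, "cv_curve") &&
                  any(grepl("_sd$", names(dynamic_curves))))
      dynamic_curves else ensemble_average(dynamic_curves)
  )
  screens <- c(total = "perf_total", left = "perf_left",
               center = "perf_center", right = "perf_right")
  rows <- list()
  for (sc in names(screens)) {
    for (mode in c("dynamic", "static")) {
      series <- ens[[mode]][[screens[[sc]]]]
      dw <- durbin_watson(series)
      mk <- mann_kendall(series)
      sen <- sens_slope(series, conf_level)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mode = mode, screen = sc,
        dw_d = dw$D, dw_lower = dw$d_lower, dw_upper = dw$d_upper,
        dw_autocorrelation = dw$du_rule_significant, dw_verdict = dw$verdict,
        mk_s = mk$S, mk_se = mk$se, mk_z = mk$Z, mk_p = mk$p_value,
        trend = mk$direction,
        sen_slope = sen$slope, sen_lower = sen$ci_lower, sen_upper = sen$ci_upper
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "n_buckets") <- nrow(ens$static)
  attr(res, "conf_level") <- conf_level
  class(res) <- c("cv_trend_report", class(res))
  res
}

#' Publication-shaped trend table
#'
#' Transposes a [trend_report()] into the published layout: 13 statistic rows
#' by 8 result columns (dynamic/static x all-screens/left/center/right), with
#' numbers formatted to 3 decimals.
#'
#' @param report A `cv_trend_report`.
#' @return A tibble with a `statistic` column and 8 result columns.
#' @export
trend_report_table <- function(report) {
  if (!inherits(report, "cv_trend_report")) {
    cv_abort("`report` must come from trend_report().", "bad_argument")
  }
  col_name <- function(mode, screen) {
    paste0(mode, "_", ifelse(screen == "total", "all_screens", screen))
  }
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  stats_rows <- c(
    "Durbin-Watson D statistic", "D-lower", "D-upper",
    "Significant autocorrelation (D < d_upper)", "Autocorrelation verdict",
    "Mann-Kendall S statistic", "Standard error", "Z statistic", "P-value",
    "Trend", "Sen's slope", "Slope CI lower", "Slope CI upper"
  )
  out <- tibble::tibble(statistic = stats_rows)
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    out[[col_name(r$mode, r$screen)]] <- c(
      fmt(r$dw_d), fmt(r$dw_lower), fmt(r$dw_upper),
      ifelse(r$dw_autocorrelation, "yes", "no"), r$dw_verdict,
      fmt(r$mk_s), fmt(r$mk_se), fmt(r$mk_z), format.pval(r$mk_p, digits = 3),
      r$trend, fmt(r$sen_slope), fmt(r$sen_lower), fmt(r$sen_upper)
    )
  }
  out
}

#' Write a trend report as TSV
#'
#' @param report A `cv_trend_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trend_report <- function(report, path) {
  readr::write_tsv(trend_report_table(report), path)
  invisible(path)
}
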