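test_that("Mann-Kendall matches brute-force enumeration and known values", {
  # brute-force oracle over explicit pairs, random short series (with ties)
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:8, 1)
    x <- sample(c(rnorm(6), 1, 1), n, replace = TRUE)
    expect_identical(mann_kendall(x)$S, mk_brute_s(x))
  }

  # strictly increasing: S is the number of pairs
  expect_equal(mann_kendall(c(1, 2, 3, 4))$S, 6)
  expect_equal(mk_brute_s(c(1, 2, 3)), 3)
  # direction requires significance; at n = 8 a monotone rise clears p < .05
  expect_equal(mann_kendall(1:8)$direction, "positive")

  # untied n = 30 null standard error (3-decimal reference 56.051)
  mk <- mann_kendall(seq_len(30) + c(0.2, -0.2))
  expect_equal(mk$se, sqrt(30 * 29 * 65 / 18))
  expect_equal(round(mk$se, 3), 56.051)

  expect_error(mann_kendall(c(1, 2, 3)), class = "cybervig_bad_argument")
})

test_that("Mann-Kendall respects symmetry, ties and missing values", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(5:12, 1))
    expect_equal(mann_kendall(rev(x))$S, -mann_kendall(x)$S)
  }
  # independent cross-check against base R Kendall tau on untied data
  x <- rnorm(15)
  tau <- unname(stats::cor.test(seq_along(x), x, method = "kendall")$estimate)
  expect_equal(mann_kendall(x)$S, tau * choose(15, 2))

  # tie correction shrinks the variance
  tied <- c(1, 2, 2, 3, 3, 3, 4)
  untied_var <- 7 * 6 * 19 / 18
  expect_lt(mann_kendall(tied)$var_S, untied_var)

  # missing values drop pairs
  x <- c(1, NA, 2, 5, 3, NA, 4)
  expect_identical(mann_kendall(x)$S, mk_brute_s(x))
  expect_equal(mann_kendall(x)$n, 5)

  # constant series: S = 0, Z = 0, no direction
  mk0 <- mann_kendall(rep(2, 6))
  expect_equal(mk0$S, 0)
  expect_equal(mk0$Z, 0)
  expect_equal(mk0$direction, "none")
})

test_that("Sen's slope matches enumeration, linearity and equivariance", {
  # explicit 3-pair enumeration {-2, -0.5, 1} -> median -0.5 (via oracle)
  expect_equal(sen_brute(c(3, 1, 2)), -0.5)
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(sample(4:8, 1))
    expect_equal(sens_slope(x)$slope, sen_brute(x), tolerance = 1e-12)
  }

  # perfectly linear series: slope exact, CI degenerate
  x <- 2 + 0.5 * (1:12)
  sen <- sens_slope(x)
  expect_equal(sen$slope, 0.5)
  expect_equal(sen$ci_lower, 0.5)
  expect_equal(sen$ci_upper, 0.5)

  expect_equal(sens_slope(rep(3, 8))$slope, 0)

  # shift/scale equivariance: slope(a + b x) = b slope(x)
  set.seed(12)
  x <- rnorm(15)
  expect_equal(sens_slope(5 - 2.5 * x)$slope, -2.5 * sens_slope(x)$slope,
               tolerance = 1e-12)

  # missing values widen the pair spacing (positions kept)
  x <- c(1, NA, 3, 4, 6)
  expect_equal(sens_slope(x)$slope, sen_brute(x), tolerance = 1e-12)

  # CI brackets the estimate
  set.seed(13)
  y <- 0.3 * (1:30) + rnorm(30)
  sen <- sens_slope(y)
  expect_lte(sen$ci_lower, sen$slope)
  expect_gte(sen$ci_upper, sen$slope)
})

test_that("Durbin-Watson statistic, bounds and verdicts behave as published", {
  # direct arithmetic on a residual vector: [1,-1,1,-1] -> 12/4 = 3
  expect_equal(cybervig:::dw_statistic(c(1, -1, 1, -1)), 3)

  bd <- dw_bounds(30)
  expect_equal(unname(bd), c(1.352, 1.489))
  expect_lt(bd[["d_lower"]], bd[["d_upper"]])
  expect_error(dw_bounds(10), class = "cybervig_bad_argument")

  # D in [0, 4] across random series; ~2 under independence
  set.seed(21)
  dd <- replicate(50, durbin_watson(rnorm(30))$D)
  expect_true(all(dd >= 0 & dd <= 4))

  # strongly positively autocorrelated residuals depress D below white noise
  set.seed(22)
  d_ar <- replicate(40, {
    e <- as.numeric(stats::arima.sim(list(ar = 0.9), 30))
    durbin_watson(e)$D
  })
  expect_gt(mean(replicate(40, durbin_watson(rnorm(30))$D) > d_ar), 0.9)

  # the published total-task static value 1.178 < d_lower = 1.352 at n = 30
  set.seed(23)
  found <- FALSE
  for (i in 1:200) {
    x <- as.numeric(stats::arima.sim(list(ar = 0.8), 30))
    dw <- durbin_watson(x)
    if (abs(dw$D - 1.178) < 0.17) {
      expect_equal(dw$verdict, "positive_autocorrelation")
      expect_true(dw$du_rule_significant)
      found <- TRUE
      break
    }
  }
  expect_true(found)

  expect_error(durbin_watson(1:30), class = "cybervig_degenerate")  # perfect fit
  expect_error(durbin_watson(rnorm(5)), class = "cybervig_bad_argument")
})

test_that("split-half reliability hits the textbook cases", {
  x <- numeric(60)
  x[seq(1, 59, 2)] <- 1:30
  x[seq(2, 60, 2)] <- 1:30
  expect_equal(split_half_reliability(x), 1)

  y <- x
  y[seq(2, 60, 2)] <- 100 - (1:30)
  expect_equal(split_half_reliability(y), -1)

  expect_error(split_half_reliability(rep(50, 60)), class = "cybervig_degenerate")
  expect_error(split_half_reliability(rnorm(59)), class = "cybervig_bad_argument")
  z <- x; z[5] <- NA
  expect_error(split_half_reliability(z), class = "cybervig_bad_argument")
})

test_that("the trend report has the published shape and internal consistency", {
  set.seed(31)
  fake_curve <- function(slope) {
    cur <- tibble::tibble(
      bucket = 0:29, start_min = 2 * (0:29),
      perf_left = 70 + slope * (0:29) + rnorm(30),
      perf_center = 75 + slope * (0:29) + rnorm(30),
      perf_right = 65 + slope * (0:29) + rnorm(30)
    )
    cur$perf_total <- (cur$perf_left + cur$perf_center + cur$perf_right) / 3
    attr(cur, "width") <- 2
    class(cur) <- c("cv_curve", class(cur))
    cur
  }
  rep_obj <- trend_report(
    static_curves = list(fake_curve(0.4), fake_curve(0.5)),
    dynamic_curves = list(fake_curve(-0.5), fake_curve(-0.4))
  )
  expect_equal(nrow(rep_obj), 8L)
  stat_cols <- setdiff(names(rep_obj), c("mode", "screen"))
  expect_length(stat_cols, 13L)
  expect_equal(rep_obj$mode[1:2], c("dynamic", "static"))
  expect_true(all(rep_obj$trend[rep_obj$mode == "static"] == "positive"))
  expect_true(all(rep_obj$trend[rep_obj$mode == "dynamic"] == "negative"))

  # Z = (S -/+ 1)/se in every column
  expect_equal(rep_obj$mk_z,
               ifelse(rep_obj$mk_s > 0, (rep_obj$mk_s - 1) / rep_obj$mk_se,
                      ifelse(rep_obj$mk_s < 0, (rep_obj$mk_s + 1) / rep_obj$mk_se, 0)))

  tab <- trend_report_table(rep_obj)
  expect_equal(dim(tab), c(13L, 9L))
  expect_equal(names(tab)[2], "dynamic_all_screens")

  tidy_rep <- tidy(rep_obj)
  expect_s3_class(tidy_rep, "tbl_df")
  expect_equal(nrow(tidy_rep), 8L)
})

test_that("tidiers return one-row summaries", {
  x <- c(1, 3, 2, 5, 4, 6, 7)
  expect_equal(tidy(mann_kendall(x))$statistic, mk_brute_s(x))
  expect_equal(tidy(sens_slope(x))$estimate, sen_brute(x))
  dw <- durbin_watson(rnorm(20) + 0.1 * (1:20))
  expect_named(tidy(dw),
               c("statistic", "d_lower", "d_upper", "verdict",
                 "du_rule_significant", "n"))
})
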