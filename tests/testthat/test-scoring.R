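test_that("outcomes land in half-open buckets and counts are conserved", {
  o <- tibble::tibble(
    timestamp_s = c(0, 119.999, 120, 240, 359.9),
    screen = c("left", "left", "center", "right", "left"),
    outcome = c("hit", "miss", "hit", "false_alarm", "hit"),
    signal_id = c("L1", "L2", "C1", NA, "L3")
  )
  counts <- bucket_counts(fake_log(o, duration = 6), width = 2)
  expect_equal(nrow(counts), 9L)  # 3 buckets x 3 screens
  b0 <- counts[counts$bucket == 0 & counts$screen == "left", ]
  expect_equal(c(b0$hits, b0$misses), c(1L, 1L))
  # an outcome at exactly 120 s belongs to bucket 1, not 0
  expect_equal(counts$hits[counts$bucket == 1 & counts$screen == "center"], 1L)
  expect_equal(sum(counts$hits) + sum(counts$misses) + sum(counts$false_alarms),
               nrow(o))

  empty <- bucket_counts(fake_log(o[0, ], duration = 6), width = 2)
  expect_true(all(empty$hits == 0 & empty$misses == 0 & empty$false_alarms == 0))

  expect_error(bucket_counts(fake_log(o, duration = 6), width = 3.5),
               class = "cybervig_bad_argument")

  # a 60-minute log yields the standard 30-bucket series
  o60 <- tibble::tibble(timestamp_s = 1800, screen = "left",
                        outcome = "hit", signal_id = "L1")
  expect_equal(nrow(bucket_counts(fake_log(o60, duration = 60), 2)) / 3, 30)
})

test_that("detection percentages follow the per-screen and pooled formulas", {
  mk_o <- function(screen, outcome, n, t = 30) {
    tibble::tibble(timestamp_s = rep(t, n), screen = screen,
                   outcome = outcome, signal_id = NA_character_)
  }
  o <- dplyr::bind_rows(
    mk_o("left", "hit", 3), mk_o("left", "miss", 1),
    mk_o("center", "hit", 8), mk_o("center", "miss", 2),
    mk_o("center", "false_alarm", 2),
    mk_o("right", "hit", 1), mk_o("right", "false_alarm", 1)
  )
  cur <- vigilance_curve(fake_log(o, duration = 2), width = 2)
  expect_equal(cur$perf_left, 75)
  expect_equal(cur$perf_center, 100 * 8 / 12)
  expect_equal(cur$perf_right, 50)
  # pooled total, not the mean of screen percentages
  expect_equal(cur$perf_total, 100 * 12 / 18, tolerance = 1e-12)

  # second worked example: L (2,1,0), C (8,2,2), R (1,0,1) -> 100*11/17
  o2 <- dplyr::bind_rows(
    mk_o("left", "hit", 2), mk_o("left", "miss", 1),
    mk_o("center", "hit", 8), mk_o("center", "miss", 2),
    mk_o("center", "false_alarm", 2),
    mk_o("right", "hit", 1), mk_o("right", "false_alarm", 1)
  )
  cur2 <- vigilance_curve(fake_log(o2, duration = 2), width = 2)
  expect_equal(cur2$perf_total, 100 * 11 / 17, tolerance = 1e-12)

  # all-hit log scores 100 everywhere; empty buckets are missing
  o3 <- mk_o("left", "hit", 5, t = 30)
  cur3 <- vigilance_curve(fake_log(o3, duration = 4), width = 2)
  expect_equal(cur3$perf_left[1], 100)
  expect_true(is.na(cur3$perf_left[2]))
  expect_true(is.na(cur3$perf_total[2]))
})

test_that("simulated-log percentages stay in range and refine consistently", {
  log <- run_trial(quick_config("dynamic", duration = 8, seed = 3),
                   operator_params(), 4)
  c2 <- bucket_counts(log, 2)
  c1 <- bucket_counts(log, 1)
  lab <- c(hits = "hit", misses = "miss", false_alarms = "false_alarm")
  for (col in names(lab)) {
    # conservation against the raw log
    expect_equal(sum(c2[[col]]), sum(log$outcomes$outcome == lab[[col]]))
    # 2-minute buckets are the sum of their two 1-minute refinements
    expect_equal(c2[[col]],
                 c1[[col]][c1$bucket %% 2 == 0] + c1[[col]][c1$bucket %% 2 == 1])
  }
  cur <- detection_percentages(c2)
  vals <- unlist(cur[c("perf_left", "perf_center", "perf_right", "perf_total")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
})

test_that("minute series equals the width-1 pooled curve and needs 60 minutes", {
  log <- run_trial(quick_config("static", duration = 60, seed = 2),
                   operator_params(), 3)
  mins <- minute_detection_series(log)
  expect_equal(nrow(mins), 60L)
  expect_equal(mins$perf, vigilance_curve(log, width = 1)$perf_total)

  short <- run_trial(quick_config("static", duration = 4, seed = 2),
                     operator_params(), 3)
  expect_error(minute_detection_series(short), class = "cybervig_bad_argument")
})

test_that("ensemble averaging returns means and standard deviations", {
  base <- tibble::tibble(
    timestamp_s = c(30, 30, 150, 150), screen = "left",
    outcome = c("hit", "miss", "hit", "hit"),
    signal_id = c("L1", "L2", "L3", "L4")
  )
  c1 <- vigilance_curve(fake_log(base, duration = 4), 2)         # 50, 100
  base2 <- base; base2$outcome <- c("hit", "hit", "hit", "miss") # 100, 50
  c2 <- vigilance_curve(fake_log(base2, duration = 4), 2)

  ens <- ensemble_average(list(c1, c2))
  expect_equal(ens$perf_left, c(75, 75))
  expect_equal(ens$perf_left_sd, rep(sd(c(50, 100)), 2))

  same <- ensemble_average(list(c1, c1))
  expect_equal(same$perf_left, c1$perf_left)
  expect_equal(same$perf_left_sd, c(0, 0))

  single <- ensemble_average(list(c1))
  expect_equal(single$perf_left, c1$perf_left)

  c_bad <- vigilance_curve(fake_log(base, duration = 6), 2)
  expect_error(ensemble_average(list(c1, c_bad)), class = "cybervig_bad_argument")
})
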