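test_that("stimulus streams are sorted, bounded and seed-deterministic", {
  cfg <- quick_config("static", duration = 10, seed = 21)
  stim <- generate_stimulus_stream(cfg)
  expect_true(all(diff(stim$timestamp_s) >= 0))
  expect_true(all(stim$timestamp_s >= 0 & stim$timestamp_s <= 600))
  expect_identical(stim, generate_stimulus_stream(cfg))

  onsets <- stim[stim$kind == "flicker_onset", ]
  # constant-rate Poisson with mean 16/min: 160 expected over 10 min
  expect_gt(nrow(onsets), 100)
  expect_lt(nrow(onsets), 230)
  expect_true(all(onsets$flicker_hz == 48))  # static salience constant

  dyn <- generate_stimulus_stream(quick_config("dynamic", duration = 10, seed = 21))
  donsets <- dyn[dyn$kind == "flicker_onset", ]
  # dynamic salience follows the ramp at each onset time
  sch <- workload_schedule("dynamic", duration = 10)
  expect_equal(donsets$flicker_hz, salience_at(sch, donsets$timestamp_s / 60))
})

test_that("left-screen macro actions classify as hit / false alarm / timeout miss", {
  st <- new_trial_state(mech_config())
  inject_stimulus(st, 5, "flicker_onset", icon = 7)
  out <- apply_action(st, 6, "macro_ctrl_d")
  expect_equal(out$outcome, "hit")
  expect_equal(out$screen, "left")
  expect_false(st$flicker_active[7])  # icon reverted to green

  out2 <- apply_action(st, 7, "macro_ctrl_d")  # nothing flickering
  expect_equal(out2$outcome, "false_alarm")
  expect_true(is.na(out2$signal_id))

  # unanswered flicker times out to exactly one miss
  inject_stimulus(st, 100, "flicker_onset", icon = 2)
  expect_equal(nrow(advance_time(st, 109)), 0L)
  out3 <- advance_time(st, 111)
  expect_equal(out3$outcome, "miss")
  expect_equal(out3$timestamp_s, 110)
  expect_equal(nrow(advance_time(st, 200)), 0L)

  # oldest active flicker is consumed first
  inject_stimulus(st, 201, "flicker_onset", icon = 1)
  inject_stimulus(st, 202, "flicker_onset", icon = 2)
  hit <- apply_action(st, 203, "macro_ctrl_d")
  expect_equal(hit$signal_id, "L3")  # third onset in this state, first still active
  expect_false(st$flicker_active[1])
  expect_true(st$flicker_active[2])
})

test_that("center ratings classify against the SSLBL priority and grow charts", {
  st <- new_trial_state(mech_config())
  inject_stimulus(st, 1, "alert_arrival", ip = ip_string(3, 3), priority = 3)
  out <- apply_action(st, 2, "rate_alert", score = 2)
  expect_equal(out$screen, "center")
  expect_equal(out$outcome, "false_alarm")  # overestimated severity
  expect_equal(chart_counts(st)[3, 3], 1L)  # true-type chart incremented

  inject_stimulus(st, 3, "alert_arrival", ip = ip_string(2, 5), priority = 2)
  expect_equal(apply_action(st, 4, "rate_alert", score = 2)$outcome, "hit")
  inject_stimulus(st, 5, "alert_arrival", ip = ip_string(2, 5), priority = 2)
  expect_equal(apply_action(st, 6, "rate_alert", score = 4)$outcome, "miss")
  expect_equal(chart_counts(st)[2, 5], 2L)

  expect_error(apply_action(st, 7, "rate_alert", score = 1),
               class = "cybervig_state")  # queue empty
})

test_that("right-screen breaches open at threshold, resolve once, and reset", {
  st <- new_trial_state(mech_config())
  ip <- ip_string(1, 5)  # priority-1 chart, threshold 3
  inject_stimulus(st, 1, "ai_injection", ip = ip, increment = 2)
  expect_equal(nrow(open_breaches(st)), 0L)

  # the operator-driven increment crosses the threshold
  inject_stimulus(st, 2, "alert_arrival", ip = ip, priority = 1)
  apply_action(st, 3, "rate_alert", score = 1)
  expect_equal(chart_counts(st)[1, 5], 3L)
  expect_equal(open_breaches(st)$ip, ip)

  hit <- apply_action(st, 5, "admin_alert", ip = ip)
  expect_equal(hit$screen, "right")
  expect_equal(hit$outcome, "hit")
  expect_equal(chart_counts(st)[1, 5], 0L)
  expect_equal(nrow(open_breaches(st)), 0L)

  # wrong IP / no breach -> right false alarm
  fa <- apply_action(st, 6, "admin_alert", ip = ip_string(4, 1))
  expect_equal(fa$outcome, "false_alarm")

  # unanswered breach times out within breach_timeout (15 s)
  inject_stimulus(st, 200, "ai_injection", ip = ip, increment = 3)
  expect_equal(nrow(open_breaches(st)), 1L)
  expect_equal(nrow(advance_time(st, 214)), 0L)
  miss <- advance_time(st, 216)
  expect_equal(miss$outcome, "miss")
  expect_equal(miss$timestamp_s, 215)
  expect_equal(chart_counts(st)[1, 5], 0L)
})

test_that("degenerate operators bound the trial outcomes", {
  cfg <- quick_config("static", duration = 4, seed = 33)
  log_p <- run_trial(cfg, perfect_operator(), 7)
  expect_equal(sum(log_p$outcomes$outcome == "miss"), 0L)
  expect_equal(sum(log_p$outcomes$outcome == "false_alarm"), 0L)

  log_i <- run_trial(cfg, inert_operator(), 7)
  left <- log_i$outcomes[log_i$outcomes$screen == "left", ]
  n_presented <- sum(!is.na(log_i$stimuli$icon) &
                       log_i$stimuli$kind == "flicker_onset")
  expect_equal(sum(left$outcome == "miss"), n_presented)
  expect_equal(sum(left$outcome == "hit"), 0L)
})

test_that("every presented signal resolves exactly once", {
  for (mode in c("static", "dynamic")) {
    log <- run_trial(quick_config(mode, duration = 10, seed = 11), operator_params(), 13)
    o <- log$outcomes

    # signal ids never appear twice
    ids <- o$signal_id[!is.na(o$signal_id)]
    expect_equal(anyDuplicated(ids), 0L)

    # left: hits + misses == presented (non-dropped) onsets
    presented <- log$stimuli$kind == "flicker_onset" & !is.na(log$stimuli$icon)
    left <- o[o$screen == "left", ]
    expect_equal(sum(left$outcome %in% c("hit", "miss") & !is.na(left$signal_id)),
                 sum(presented))

    # center: one outcome per presented alert
    expect_equal(sum(o$screen == "center" & !is.na(o$signal_id)),
                 sum(log$stimuli$kind == "alert_arrival"))

    # right: every breach id resolves as hit or miss
    rb <- o[o$screen == "right" & !is.na(o$signal_id), ]
    expect_true(all(rb$outcome %in% c("hit", "miss")))

    # left/right false alarms carry no signal id (there was no signal);
    # center false alarms are the single resolution of a real alert and
    # keep its id
    fa <- o[o$outcome == "false_alarm", ]
    expect_true(all(is.na(fa$signal_id[fa$screen != "center"])))
    expect_true(all(!is.na(o$signal_id[o$screen == "center"])))
  }
})

test_that("chart replay confirms threshold and near-critical bookkeeping", {
  for (spec in list(c("static", 6), c("dynamic", 20))) {
    log <- run_trial(quick_config(spec[1], duration = as.numeric(spec[2]), seed = 5),
                     operator_params(), 6)
    rep <- replay_charts(log)
    expect_true(rep$ok_threshold)
    expect_true(rep$ok_nc)
    expect_equal(rep$n_breach_replayed, rep$n_breach_logged)
  }
})

test_that("identical seeds give bit-identical logs", {
  cfg <- quick_config("dynamic", duration = 10, seed = 17)
  op <- operator_params()
  log1 <- run_trial(cfg, op, 23)
  log2 <- run_trial(cfg, op, 23)
  expect_identical(log1, log2)

  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_trial_log(log1, f1)
  write_trial_log(log2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different operator seed changes the log
  log3 <- run_trial(cfg, op, 24)
  expect_false(identical(log1$outcomes, log3$outcomes))
})

test_that("the strict miss rule logs extra left misses on concurrent actions", {
  st <- new_trial_state(mech_config(strict_miss_rule = TRUE))
  inject_stimulus(st, 1, "flicker_onset", icon = 3)
  inject_stimulus(st, 2, "alert_arrival", ip = ip_string(2, 1), priority = 2)
  out <- apply_action(st, 3, "rate_alert", score = 2)
  expect_true(any(out$screen == "left" & out$outcome == "miss" & is.na(out$signal_id)))
  expect_true(any(out$screen == "center" & out$outcome == "hit"))
})
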