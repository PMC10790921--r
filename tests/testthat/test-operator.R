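test_that("response probability reduces to its parts", {
  sch <- workload_schedule("dynamic")
  flat <- operator_params(
    base_detect = c(left = 0.9, center = 0.9, right = 0.9),
    salience_coeff = 0, rate_coeff = 0, load_coeff = 0,
    learn_coeff = 0, fatigue_coeff = 0
  )
  t <- seq(0, 60, by = 5)
  expect_equal(response_probability(flat, "left", sch, t), rep(0.9, length(t)))

  learner <- operator_params(
    base_detect = c(left = 0.5, center = 0.5, right = 0.5),
    salience_coeff = 0, rate_coeff = 0, load_coeff = 0,
    learn_coeff = 0.2, fatigue_coeff = 0
  )
  p <- response_probability(learner, "center", sch, t)
  expect_true(all(diff(p) > 0))

  # shipped dynamic defaults: rising workload wins over learning by t = 60
  dflt <- operator_params()
  expect_lt(response_probability(dflt, "left", sch, 60),
            response_probability(dflt, "left", sch, 0))
})

test_that("combined probabilities always respect the clamp", {
  sch_d <- workload_schedule("dynamic")
  sch_s <- workload_schedule("static")
  set.seed(42)
  for (i in 1:50) {
    op <- operator_params(
      base_detect = c(left = runif(1), center = runif(1), right = runif(1)),
      salience_coeff = runif(1, -0.5, 0.5), rate_coeff = runif(1, -0.5, 0.5),
      load_coeff = runif(1, -0.5, 0.5), learn_coeff = runif(1, -0.5, 0.5),
      fatigue_coeff = runif(1, -0.5, 0.5)
    )
    for (sch in list(sch_d, sch_s)) {
      p <- response_probability(op, sample(c("left", "center", "right"), 1),
                                sch, seq(0, 60, by = 3))
      expect_true(all(p >= 0.02 & p <= 0.98))
    }
  }
})

test_that("simulate_responses covers the degenerate operators", {
  cfg <- quick_config("static", duration = 4)
  stim <- generate_stimulus_stream(cfg)
  onsets <- sum(stim$kind == "flicker_onset")

  acts <- simulate_responses(perfect_operator(), stim, cfg, seed = 5)
  expect_equal(nrow(acts), onsets)  # every signal answered, no false alarms
  expect_true(all(acts$action == "macro_ctrl_d"))

  none <- simulate_responses(inert_operator(), stim, cfg, seed = 5)
  expect_equal(nrow(none), 0L)

  a1 <- simulate_responses(operator_params(), stim, cfg, seed = 9)
  a2 <- simulate_responses(operator_params(), stim, cfg, seed = 9)
  expect_identical(a1, a2)
})

test_that("cohorts are counterbalanced and reproducible", {
  coh <- simulate_cohort(2, base_seed = 3, duration = 2)
  expect_equal(length(coh$logs), 4L)
  expect_equal(sort(unique(coh$manifest$order)),
               c("dynamic_first", "static_first"))
  orders <- unique(coh$manifest[c("participant", "order")])
  expect_equal(as.vector(table(orders$order)), c(1L, 1L))

  coh2 <- simulate_cohort(2, base_seed = 3, duration = 2)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$logs, coh2$logs)

  expect_error(simulate_cohort(1, base_seed = 1), class = "cybervig_bad_argument")

  # odd n splits ceiling/floor
  coh5 <- simulate_cohort(5, base_seed = 1, duration = 2)
  orders5 <- unique(coh5$manifest[c("participant", "order")])
  expect_equal(sum(orders5$order == "static_first"), 3L)
  expect_equal(sum(orders5$order == "dynamic_first"), 2L)
})
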