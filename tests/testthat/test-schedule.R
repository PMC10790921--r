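test_that("dynamic schedules ramp linearly between the stated bounds", {
  dyn <- workload_schedule("dynamic")
  expect_equal(salience_at(dyn, 0), 20)
  expect_equal(salience_at(dyn, 60), 48)
  expect_equal(salience_at(dyn, 30), 34)
  expect_equal(event_rate_at(dyn, 0), 8)
  expect_equal(event_rate_at(dyn, 60), 16)
  expect_equal(cognitive_load_at(dyn, 0), 1)
  expect_equal(cognitive_load_at(dyn, 60), 4)
  expect_equal(cognitive_load_at(dyn, 20), 2)

  # exact closed-form linearity against the printed slopes
  t <- seq(0, 60, by = 0.25)
  expect_equal(salience_at(dyn, t), 7 / 15 * t + 20)
  expect_equal(event_rate_at(dyn, t), 2 / 15 * t + 8)
  expect_equal(cognitive_load_at(dyn, t), 1 / 20 * t + 1)
})

test_that("static schedules hold the most difficult processing values", {
  sta <- workload_schedule("static")
  t <- c(0, 17.3, 42, 60)
  expect_equal(salience_at(sta, t), rep(48, 4))
  expect_equal(event_rate_at(sta, t), rep(16, 4))
  expect_equal(cognitive_load_at(sta, t), rep(4, 4))
})

test_that("dynamic endpoint equals the static constants, components monotone", {
  dyn <- workload_schedule("dynamic")
  sta <- workload_schedule("static")
  expect_equal(unlist(workload_at(dyn, 60)[-1]), unlist(workload_at(sta, 33.3)[-1]))
  expect_equal(unlist(workload_at(dyn, 0)[-1]),
               c(salience_hz = 20, event_rate = 8, cognitive_load = 1))
  t <- sort(runif(50, 0, 60))
  for (f in list(salience_at, event_rate_at, cognitive_load_at)) {
    expect_true(all(diff(f(dyn, t)) >= 0))
  }
})

test_that("times outside the trial raise a domain error", {
  dyn <- workload_schedule("dynamic", duration = 60)
  expect_error(salience_at(dyn, -0.1), class = "cybervig_domain")
  expect_error(event_rate_at(dyn, 60.1), class = "cybervig_domain")
  expect_error(workload_at(dyn, 1e3), class = "cybervig_domain")
  expect_error(workload_schedule("dynamic", duration = 0),
               class = "cybervig_bad_argument")
  expect_error(workload_schedule("dynamic", salience_bounds = c(48, 20)),
               class = "cybervig_bad_argument")
})

test_that("the integer load target steps at half-count crossings", {
  dyn <- workload_schedule("dynamic")
  steps <- cybervig:::load_target_steps(dyn)
  expect_equal(steps$t, c(0, 10, 30, 50))
  expect_equal(steps$target, 1:4)
  sta <- workload_schedule("static")
  expect_equal(cybervig:::load_target_steps(sta)$target, 4)
})
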