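#' Synthetic operator parameters
#'
#' The operator model converts stimulus streams into plausible action streams.
#' It is *not* part of the task design itself: it stands in for human
#' participants so that the scoring and trend-analysis pipeline has a test
#' surface. Detection of each signal is a Bernoulli draw at a per-screen
#' response probability that combines a baseline with a learning gain, a
#' fatigue loss driven by cumulative workload, and penalties proportional to
#' the instantaneous normalized salience / event-rate / cognitive-load
#' components (see [response_probability()]). The shipped defaults are
#' calibrated so that, purely through the asymmetry between constant-maximum
#' (static) and ramping (dynamic) workload, cohorts reproduce the direction of
#' the validation findings: improvement under static workload, decrement under
#' dynamic workload.
#'
#' @param base_detect Named length-3 probability vector (`left`, `center`,
#'   `right`): detection baseline per screen before modifiers.
#' @param salience_coeff,rate_coeff,load_coeff Probability penalty applied per
#'   unit of the corresponding normalized (0-1) workload component.
#' @param learn_coeff Probability gained per hour on task (practice effect).
#' @param fatigue_coeff Probability lost per unit cumulative normalized
#'   workload (one unit = one hour at maximum workload).
#' @param false_alarm_rate Named length-3 rate vector, spurious actions per
#'   minute per screen. Center false alarms arise from rating errors rather
#'   than a spontaneous stream, so the center rate defaults to 0.
#' @param latency_meanlog,latency_sdlog Log-normal response-latency parameters
#'   (seconds) for left/right signal responses.
#' @param service_meanlog,service_sdlog Log-normal center-screen alert service
#'   time (seconds); floored at the trial configuration's
#'   `center_service_floor`.
#' @param clamp Length-2 bounds applied to the combined response probability
#'   (default `c(0.02, 0.98)`). Degenerate operators used in tests may widen
#'   this to `c(0, 1)`.
#' @return An object of class `cv_operator`.
#' @examples
#' op <- operator_params()
#' response_probability(op, "left", workload_schedule("dynamic"), c(0, 60))
#' @export
operator_params <- function(base_detect = c(left = 0.88, center = 0.92, right = 0.85),
                            salience_coeff = 0.10,
                            rate_coeff = 0.07,
                            load_coeff = 0.08,
                            learn_coeff = 0.15,
                            fatigue_coeff = 0.05,
                            false_alarm_rate = c(left = 0.5, center = 0, right = 0.2),
                            latency_meanlog = log(1.2),
                            latency_sdlog = 0.35,
                            service_meanlog = log(2.8),
                            service_sdlog = 0.30,
                            clamp = c(0.02, 0.98)) {
  screens <- c("left", "center", "right")
  base_detect <- unlist(base_detect)
  false_alarm_rate <- unlist(false_alarm_rate)
  if (length(base_detect) != 3L || !all(screens %in% names(base_detect))) {
    cv_abort("`base_detect` must be named (left, center, right).", "bad_argument")
  }
  if (length(false_alarm_rate) != 3L || !all(screens %in% names(false_alarm_rate))) {
    cv_abort("`false_alarm_rate` must be named (left, center, right).", "bad_argument")
  }
  if (any(base_detect < 0 | base_detect > 1)) {
    cv_abort("`base_detect` entries must be probabilities.", "bad_argument")
  }
  if (any(false_alarm_rate < 0)) {
    cv_abort("`false_alarm_rate` entries must be >= 0.", "bad_argument")
  }
  for (nm in c("salience_coeff", "rate_coeff", "load_coeff",
               "learn_coeff", "fatigue_coeff")) {
    check_number(get(nm), nm, lower = -1, upper = 1)
  }
  check_number(latency_sdlog, "latency_sdlog", lower = 1e-12)
  check_number(service_sdlog, "service_sdlog", lower = 1e-12)
  if (!is.numeric(clamp) || length(clamp) != 2L || clamp[1] > clamp[2] ||
      clamp[1] < 0 || clamp[2] > 1) {
    cv_abort("`clamp` must be probability bounds (lo <= hi).", "bad_argument")
  }
  structure(
    list(
      base_detect = base_detect[screens],
      salience_coeff = salience_coeff,
      rate_coeff = rate_coeff,
      load_coeff = load_coeff,
      learn_coeff = learn_coeff,
      fatigue_coeff = fatigue_coeff,
      false_alarm_rate = false_alarm_rate[screens],
      latency_meanlog = latency_meanlog,
      latency_sdlog = latency_sdlog,
      service_meanlog = service_meanlog,
      service_sdlog = service_sdlog,
      clamp = as.numeric(clamp)
    ),
    class = "cv_operator"
  )
}

#' @export
print.cv_operator <- function(x, ...) {
  cat("<cv_operator>\n")
  cat("  base detect :",
      paste(sprintf("%s=%.2f", names(x$base_detect), x$base_detect), collapse = " "),
      "\n")
  cat(sprintf("  learn %.3f/h  fatigue %.3f/unit  penalties S=%.3f E=%.3f C=%.3f\n",
              x$learn_coeff, x$fatigue_coeff,
              x$salience_coeff, x$rate_coeff, x$load_coeff))
  cat("  false alarms/min:",
      paste(sprintf("%s=%.2f", names(x$false_alarm_rate), x$false_alarm_rate),
            collapse = " "), "\n")
  invisible(x)
}

check_operator <- function(params) {
  if (!inherits(params, "cv_operator")) {
    cv_abort("`params` must be created with operator_params().", "bad_argument")
  }
  invisible(params)
}

# Response probability is quadratic in t for linear schedules:
# p(t) = base + learn*t/60 - fatigue*W(t) - sal*s_n(t) - rate*e_n(t) - load*c_n(t)
# Static mode: s_n = e_n = c_n = 1, W = t/60.
# Dynamic mode: s_n = e_n = c_n = t/dur, W = t^2/(120*dur).
# Returns per-screen coefficients c0 + c1*t + c2*t^2 (t in minutes), clamped at
# evaluation time.
response_prob_coefs <- function(params, schedule) {
  pen <- params$salience_coeff + params$rate_coeff + params$load_coeff
  dur <- schedule$duration
  if (schedule$mode == "static") {
    c0 <- params$base_detect - pen
    c1 <- rep(params$learn_coeff / 60 - params$fatigue_coeff / 60, 3)
    c2 <- rep(0, 3)
  } else {
    c0 <- params$base_detect
    c1 <- rep(params$learn_coeff / 60 - pen / dur, 3)
    c2 <- rep(-params$fatigue_coeff / (120 * dur), 3)
  }
  list(c0 = c0, c1 = c1, c2 = c2)
}

#' Operator response probability
#'
#' Deterministic combination of the operator's baseline detection probability
#' with a learning gain (`learn_coeff * t/60`), a fatigue loss
#' (`fatigue_coeff * W(t)`, where `W` is cumulative normalized workload in
#' hours-at-full-load), and penalties proportional to the normalized
#' instantaneous salience, event-rate and cognitive-load components. The
#' result is clamped to `params$clamp`.
#'
#' @param params An [operator_params()] object.
#' @param screen One of `"left"`, `"center"`, `"right"`.
#' @param schedule A [workload_schedule()].
#' @param t Time(s) in minutes; vectorized.
#' @return Numeric vector of probabilities.
#' @export
response_probability <- function(params, screen = c("left", "center", "right"),
                                 schedule, t) {
  check_operator(params)
  screen <- match.arg(screen)
  check_schedule(schedule)
  check_time(schedule, t)
  cf <- response_prob_coefs(params, schedule)
  i <- match(screen, c("left", "center", "right"))
  clamp(cf$c0[i] + cf$c1[i] * t + cf$c2[i] * t^2, params$clamp[1], params$clamp[2])
}

#' Simulate operator responses to a left-screen stimulus stream
#'
#' Open-loop response generation for the honeyfile (left-screen) subtask: each
#' flicker onset is detected with probability
#' `response_probability(params, "left", ...)`; detected onsets receive a
#' macro keypress after a log-normal latency, provided the latency beats the
#' flicker timeout (late detections are treated as unnoticed). Spurious macro
#' presses arrive as a homogeneous Poisson stream at the left false-alarm
#' rate. Center and right screen responses are closed-loop (they depend on
#' evolving trial state) and are generated inside [run_trial()].
#'
#' @param params An [operator_params()] object.
#' @param stimuli Stimulus tibble from [generate_stimulus_stream()] (only
#'   `kind == "flicker_onset"` rows are used).
#' @param config The [trial_config()] the stimuli were generated from.
#' @param seed Integer seed for the operator's random draws.
#' @return A tibble of actions: `timestamp_s`, `action` (`"macro_ctrl_d"`).
#' @export
simulate_responses <- function(params, stimuli, config, seed) {
  check_operator(params)
  check_config(config)
  check_number(seed, "seed", integerish = TRUE)
  set.seed(as.integer(seed))
  acts <- operator_left_actions(params, stimuli, config)
  dplyr::arrange(acts$actions, .data$timestamp_s)
}

# Internal: draws (in fixed order) detection uniforms, latencies and the left
# false-alarm stream from the *current* RNG state. Returns the action tibble
# plus per-onset press times (NA where no press) so run_trial can reuse it.
operator_left_actions <- function(params, stimuli, config) {
  onsets <- stimuli$timestamp_s[stimuli$kind == "flicker_onset"]
  n <- length(onsets)
  p <- if (n) response_probability(params, "left", config$schedule, onsets / 60) else numeric(0)
  detected <- stats::runif(n) < p
  latency <- stats::rlnorm(n, params$latency_meanlog, params$latency_sdlog)
  press <- ifelse(detected & latency <= config$flicker_timeout, onsets + latency, NA_real_)
  fa <- poisson_times(params$false_alarm_rate[["left"]] / 60,
                      config$schedule$duration * 60)
  actions <- tibble::tibble(
    timestamp_s = c(press[!is.na(press)], fa),
    action = "macro_ctrl_d"
  )
  list(actions = actions, press_times = press)
}

#' Simulate a counterbalanced cohort of participants
#'
#' Generates `n` synthetic participants, each completing one static and one
#' dynamic trial. Trial order (static-first vs dynamic-first) is
#' counterbalanced ceiling(n/2) / floor(n/2); the order label is recorded in
#' the manifest (the operator model carries no state across trials, so order
#' is metadata for downstream analyses). Each participant receives
#' multiplicative parameter jitter (+/-20% on the detection baselines and the
#' learning/fatigue/penalty coefficients) so the cohort is heterogeneous.
#'
#' @param n Number of participants (>= 2; counterbalancing needs both orders).
#' @param params_static,params_dynamic [operator_params()] used for the
#'   static and dynamic trials before per-participant jitter. The default
#'   single parameter set yields improvement under static workload and
#'   decrement under dynamic workload purely through the workload asymmetry.
#' @param base_seed Integer seed; all per-participant seeds and jitter derive
#'   from it, so identical `base_seed` gives an identical cohort.
#' @param duration Trial duration in minutes (default 60).
#' @param trial_options Named list of extra [trial_config()] arguments applied
#'   to every trial (e.g. `list(strict_miss_rule = TRUE)`).
#' @return An object of class `cv_cohort`: list with `manifest` (tibble:
#'   `participant`, `mode`, `order`, `config_seed`, `operator_seed`) and
#'   `logs` (list of [run_trial()] logs aligned with the manifest rows).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(2, base_seed = 1)
#' coh$manifest
#' }
#' @export
simulate_cohort <- function(n, params_static = operator_params(),
                            params_dynamic = params_static,
                            base_seed = 1L, duration = 60,
                            trial_options = list()) {
  check_number(n, "n", integerish = TRUE)
  if (n < 2) cv_abort("`n` must be >= 2 to counterbalance trial order.", "bad_argument")
  check_operator(params_static)
  check_operator(params_dynamic)
  check_number(base_seed, "base_seed", integerish = TRUE)

  set.seed(as.integer(base_seed))
  n <- as.integer(n)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n), ncol = 4L)
  jitter <- matrix(stats::runif(8L * n, 0.8, 1.2), ncol = 8L)

  modes <- c("static", "dynamic")
  manifest <- tibble::tibble(
    participant = rep(seq_len(n), each = 2L),
    mode = rep(modes, n),
    order = rep(ifelse(seq_len(n) %% 2L == 1L, "static_first", "dynamic_first"),
                each = 2L),
    config_seed = as.integer(t(seeds[, 1:2, drop = FALSE])),
    operator_seed = as.integer(t(seeds[, 3:4, drop = FALSE]))
  )

  logs <- vector("list", nrow(manifest))
  for (i in seq_len(n)) {
    for (m in 1:2) {
      row <- (i - 1L) * 2L + m
      base <- if (modes[m] == "static") params_static else params_dynamic
      op <- jitter_operator(base, jitter[i, ])
      cfg <- do.call(trial_config, c(
        list(schedule = workload_schedule(modes[m], duration = duration),
             seed = manifest$config_seed[row]),
        trial_options
      ))
      logs[[row]] <- run_trial(cfg, op, manifest$operator_seed[row])
    }
  }
  structure(list(manifest = manifest, logs = logs, base_seed = as.integer(base_seed)),
            class = "cv_cohort")
}

jitter_operator <- function(params, f) {
  params$base_detect <- clamp(params$base_detect * f[1:3], 0, params$clamp[2])
  params$salience_coeff <- params$salience_coeff * f[4]
  params$rate_coeff <- params$rate_coeff * f[5]
  params$load_coeff <- params$load_coeff * f[6]
  params$learn_coeff <- params$learn_coeff * f[7]
  params$fatigue_coeff <- params$fatigue_coeff * f[8]
  params
}

#' @export
print.cv_cohort <- function(x, ...) {
  cat(sprintf("<cv_cohort> %d participants, %d trial logs (base_seed %d)\n",
              max(x$manifest$participant), length(x$logs), x$base_seed))
  invisible(x)
}
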