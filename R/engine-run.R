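# Stimulus generation and the closed-loop trial runner.

# Left-screen flicker onset times: nonhomogeneous Poisson process at rate
# E(t) events/min, realized by thinning against the rate maximum. Draws from
# the current RNG state, in a fixed order shared by generate_stimulus_stream()
# and run_trial().
gen_left_onsets <- function(config) {
  sch <- config$schedule
  dur_s <- sch$duration * 60
  rate_max <- sch$event_rate_bounds[2] / 60  # events per second
  n_cand <- stats::rpois(1L, rate_max * dur_s)
  cand <- sort(stats::runif(n_cand, 0, dur_s))
  accept <- stats::runif(n_cand) <
    event_rate_at(sch, cand / 60) / sch$event_rate_bounds[2]
  t <- cand[accept]
  list(
    t = t,
    icon_u = stats::runif(length(t)),
    hz = salience_at(sch, t / 60)
  )
}

# Center alert contents, drawn from the config RNG in the order run_trial
# consumes them.
gen_alert_contents <- function(config, n) {
  list(
    priority = sample.int(nrow(config$alert_types), n, replace = TRUE),
    ip = sample.int(config$ip_pool_size, n, replace = TRUE)
  )
}

#' Generate the open-loop stimulus stream for a trial
#'
#' Produces the stimulus events that do not depend on operator behavior:
#' left-screen flicker onsets (a nonhomogeneous Poisson process at the
#' scheduled event rate, each onset assigned to a uniformly random
#' currently-green icon and carrying the scheduled flicker frequency), the
#' initial center-screen alert (the queue is self-paced: subsequent alerts are
#' presented as the operator clears them, so their times emerge in
#' [run_trial()]), and the AI chart injections that hold the number of
#' near-critical columns at the rounded cognitive-load target in the absence
#' of operator activity.
#'
#' Deterministic given `config$seed`; the onset *times* are identical to those
#' used by [run_trial()] with the same config.
#'
#' @param config A [trial_config()].
#' @return Tibble of stimulus events, time-sorted, with columns `timestamp_s`,
#'   `screen`, `kind`, `icon`, `flicker_hz`, `ip`, `priority`, `chart`,
#'   `increment`, `signal_id`.
#' @export
generate_stimulus_stream <- function(config) {
  check_config(config)
  set.seed(config$seed)
  L <- gen_left_onsets(config)
  contents <- gen_alert_contents(config, 1L)

  # open-loop icon assignment: flickers expire after the timeout
  n <- length(L$t)
  icon <- integer(n)
  active_until <- rep(-Inf, config$icon_count)
  for (i in seq_len(n)) {
    greens <- which(active_until <= L$t[i])
    if (!length(greens)) {
      icon[i] <- NA_integer_
      next
    }
    icon[i] <- greens[min(length(greens), floor(L$icon_u[i] * length(greens)) + 1L)]
    active_until[icon[i]] <- L$t[i] + config$flicker_timeout
  }

  flickers <- tibble::tibble(
    timestamp_s = L$t, screen = "left", kind = "flicker_onset",
    icon = icon, flicker_hz = L$hz,
    ip = NA_character_, priority = NA_integer_, chart = NA_integer_,
    increment = NA_integer_,
    signal_id = paste0("L", seq_len(n))
  )

  first_alert <- tibble::tibble(
    timestamp_s = 0, screen = "center", kind = "alert_arrival",
    icon = NA_integer_, flicker_hz = NA_real_,
    ip = ip_string(contents$priority[1], contents$ip[1]),
    priority = contents$priority[1], chart = NA_integer_,
    increment = NA_integer_, signal_id = "C1"
  )

  # AI injections, open loop: raise one fresh column per target unit
  steps <- load_target_steps(config$schedule)
  th <- config$admin_thresholds
  n_cols <- nrow(config$alert_types) * config$ip_pool_size
  taken <- logical(n_cols)
  inj <- list()
  n_current <- 0L
  for (s in seq_len(nrow(steps))) {
    while (n_current < steps$target[s]) {
      free <- which(!taken)
      pick <- free[min(length(free), floor(stats::runif(1) * length(free)) + 1L)]
      taken[pick] <- TRUE
      chart <- ((pick - 1L) %% nrow(config$alert_types)) + 1L
      col <- ((pick - 1L) %/% nrow(config$alert_types)) + 1L
      n_current <- n_current + 1L
      inj[[length(inj) + 1L]] <- tibble::tibble(
        timestamp_s = steps$t[s] * 60, screen = "right", kind = "ai_injection",
        icon = NA_integer_, flicker_hz = NA_real_, ip = ip_string(chart, col),
        priority = NA_integer_, chart = chart,
        increment = th[chart] - 1L, signal_id = NA_character_
      )
    }
  }
  dplyr::arrange(
    dplyr::bind_rows(flickers, first_alert, !!!inj),
    .data$timestamp_s, .data$screen
  )
}

#' Run a complete simulated trial
#'
#' Interleaves stimulus generation, the synthetic operator's responses and
#' outcome classification into a complete trial log. The left screen is
#' open-loop (flicker onsets at the scheduled event rate; operator macro
#' presses from [simulate_responses()]'s model). The center queue is
#' self-paced: each alert is presented when the previous one is rated, with
#' log-normal service times floored at the configured minimum. Every rated
#' alert grows a right-screen chart column; columns reaching their admin
#' threshold open breaches that the operator answers (or misses on timeout),
#' and the built-in AI keeps the near-critical column count on the rounded
#' cognitive-load schedule.
#'
#' Stimuli are presented only within the trial window; signals still pending
#' at the end of the window (active flickers, open breaches, the alert in
#' service) are run out to resolution so that every presented signal receives
#' exactly one outcome.
#'
#' The run is fully reproducible: identical `(config$seed, operator_seed)`
#' give bit-identical logs.
#'
#' @param config A [trial_config()].
#' @param operator An [operator_params()] model.
#' @param operator_seed Integer seed for all operator-side randomness.
#' @return An object of class `cv_trial_log`: list with `config`, `operator`,
#'   `operator_seed`, `stimuli`, `actions`, `outcomes` (tibbles, time-sorted)
#'   and `dropped_onsets`.
#' @examples
#' cfg <- trial_config(workload_schedule("static", duration = 4), seed = 7)
#' log <- run_trial(cfg, operator_params(), operator_seed = 11)
#' dplyr::count(log$outcomes, screen, outcome)
#' @export
run_trial <- function(config, operator, operator_seed) {
  check_config(config)
  check_operator(operator)
  check_number(operator_seed, "operator_seed", integerish = TRUE)
  sch <- config$schedule
  dur_s <- sch$duration * 60
  n_types <- nrow(config$alert_types)

  # --- stimulus-side draws (config seed) ---
  set.seed(config$seed)
  L <- gen_left_onsets(config)
  n_on <- length(L$t)
  nbuf <- as.integer(ceiling(dur_s / max(config$center_service_floor, 0.5))) + 10L
  contents <- gen_alert_contents(config, nbuf)

  # --- operator-side draws (operator seed) ---
  set.seed(as.integer(operator_seed))
  la <- operator_left_actions(operator, tibble::tibble(timestamp_s = L$t,
                                                       kind = "flicker_onset"),
                              config)
  press_t <- sort(la$actions$timestamp_s)

  svc <- pmax(config$center_service_floor,
              stats::rlnorm(nbuf, operator$service_meanlog, operator$service_sdlog))
  rt <- cumsum(svc)
  arrival <- c(0, rt[-nbuf])
  jmax <- sum(arrival < dur_s)  # alerts presented inside the trial window
  p_c <- response_probability(operator, "center", sch, pmin(rt[seq_len(jmax)], dur_s) / 60)
  u_corr <- stats::runif(jmax)
  u_dir <- stats::runif(jmax)
  true_pri <- contents$priority[seq_len(jmax)]
  score <- true_pri
  wrong <- u_corr >= p_c
  go_lower <- u_dir < 0.5
  score[wrong] <- ifelse(go_lower[wrong], true_pri[wrong] - 1L, true_pri[wrong] + 1L)
  score[wrong & true_pri == 1L] <- 2L
  score[wrong & true_pri == n_types] <- n_types - 1L

  fa_right_t <- poisson_times(operator$false_alarm_rate[["right"]] / 60, dur_s)
  fa_right_u <- stats::runif(length(fa_right_t))

  cf <- response_prob_coefs(operator, sch)
  steps <- load_target_steps(sch)

  # --- discrete-event core: merges the streams in time order (stimulus
  # before action, left < center < right on ties), runs the state machine and
  # the closed-loop draws (AI column choice, breach responses) ---
  core <- .run_trial_core(
    onset_t = L$t, icon_u = L$icon_u,
    press_t = press_t,
    rate_t = rt[seq_len(jmax)], rate_score = as.integer(score),
    rate_pri = as.integer(true_pri), rate_ip = as.integer(contents$ip[seq_len(jmax)]),
    fa_t = fa_right_t, fa_u = fa_right_u,
    n_types = n_types, ip_pool = config$ip_pool_size,
    icon_count = config$icon_count,
    thresholds = config$admin_thresholds,
    flicker_timeout = config$flicker_timeout,
    breach_timeout = config$breach_timeout, dur_s = dur_s,
    step_t_min = steps$t, step_v = as.integer(steps$target),
    ai_enabled = config$ai_enabled, strict_miss = config$strict_miss_rule,
    increment_by_rating = config$increment_by_rating,
    p_right_coefs = c(cf$c0[3], cf$c1[3], cf$c2[3]), clamp = operator$clamp,
    lat_meanlog = operator$latency_meanlog, lat_sdlog = operator$latency_sdlog
  )
  icon_assigned <- core$icon_assigned

  stimuli <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(
      timestamp_s = L$t, screen = "left", kind = "flicker_onset",
      icon = icon_assigned, flicker_hz = L$hz,
      ip = NA_character_, priority = NA_integer_, chart = NA_integer_,
      increment = NA_integer_, signal_id = paste0("L", seq_len(n_on))
    ),
    tibble::tibble(
      timestamp_s = arrival[seq_len(jmax)], screen = "center",
      kind = "alert_arrival",
      icon = NA_integer_, flicker_hz = NA_real_,
      ip = ip_string(true_pri, contents$ip[seq_len(jmax)]),
      priority = true_pri, chart = NA_integer_, increment = NA_integer_,
      signal_id = paste0("C", seq_len(jmax))
    ),
    tibble::tibble(
      timestamp_s = core$injections$t, screen = "right", kind = "ai_injection",
      icon = NA_integer_, flicker_hz = NA_real_,
      ip = ip_string(core$injections$chart, core$injections$ip),
      priority = NA_integer_, chart = as.integer(core$injections$chart),
      increment = as.integer(core$injections$amount), signal_id = NA_character_
    )
  ), .data$timestamp_s, .data$screen)

  actions <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(timestamp_s = press_t, action = "macro_ctrl_d",
                   score = NA_integer_, ip = NA_character_),
    tibble::tibble(timestamp_s = rt[seq_len(jmax)], action = "rate_alert",
                   score = as.integer(score), ip = NA_character_),
    tibble::tibble(timestamp_s = core$admin$t, action = "admin_alert",
                   score = NA_integer_,
                   ip = ip_string(core$admin$chart, core$admin$ip))
  ), .data$timestamp_s, .data$action)

  oc <- core$outcomes
  outcomes <- dplyr::arrange(
    tibble::tibble(
      timestamp_s = oc$t,
      screen = SCREEN_LABELS[oc$screen],
      outcome = OUTCOME_LABELS[oc$outcome],
      signal_id = ifelse(oc$idtype == 0L, NA_character_,
                         paste0(ID_PREFIX[pmax(oc$idtype, 1L)], oc$idnum))
    ),
    .data$timestamp_s, .data$screen
  )

  structure(
    list(
      config = config,
      operator = operator,
      operator_seed = as.integer(operator_seed),
      stimuli = stimuli,
      actions = actions,
      outcomes = outcomes,
      dropped_onsets = core$dropped
    ),
    class = "cv_trial_log"
  )
}

#' @export
print.cv_trial_log <- function(x, ...) {
  cat(sprintf("<cv_trial_log> %s, %g min (seed %d / operator seed %d)\n",
              x$config$schedule$mode, x$config$schedule$duration,
              x$config$seed, x$operator_seed))
  tab <- table(x$outcomes$screen, x$outcomes$outcome)
  print(tab)
  invisible(x)
}
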