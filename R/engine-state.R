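#' Trial configuration for the three-screen task engine
#'
#' Bundles the workload schedule with the task mechanics: the honeyfile icon
#' array (left screen), the five SSL-blacklist alert types with their
#' priority-dependent admin-alert thresholds (center/right screens), IP pools
#' per frequency chart, and timeout rules for unanswered signals.
#'
#' Lower priority ratings denote *more severe* threats; their anomaly
#' thresholds are correspondingly lower (priority 1 -> threshold 3 ... priority
#' 5 -> threshold 11), so severe alert categories breach sooner.
#'
#' @param schedule A [workload_schedule()].
#' @param seed Integer seed driving all stimulus-side randomness.
#' @param icon_count Number of honeyfile icons on the left screen (default 16).
#' @param alert_types Data frame with columns `name` and `priority`
#'   (1..n, unique); defaults to five operational threat categories.
#' @param admin_thresholds Integer vector, one per priority in order, strictly
#'   increasing, all >= 2: the chart column count that constitutes an anomaly.
#' @param ip_pool_size Originating IP addresses per frequency chart
#'   (default 15). IPs are unique across charts (`10.0.<chart>.<k>`).
#' @param flicker_timeout Seconds an unanswered flicker stays active before it
#'   is scored a miss and reverts to green (default 10).
#' @param breach_timeout Seconds an unanswered threshold breach stays open
#'   before it is scored a miss and the column resets (default 15).
#' @param center_service_floor Minimum center-alert service time in seconds
#'   (default 2); the operator cannot rate faster than this.
#' @param strict_miss_rule If `TRUE`, apply the literal miss rule: any
#'   non-macro action performed while at least one icon is flickering logs an
#'   additional left miss (with no signal id). The default `FALSE` resolves
#'   each signal exactly once (hit before timeout, else one miss), which keeps
#'   detection-percentage denominators interpretable.
#' @param increment_by_rating If `TRUE`, a rated alert increments the chart of
#'   the *rated* score rather than the alert's true type.
#' @param ai_enabled If `TRUE` (default) the built-in "AI" tops up
#'   near-critical chart columns so their number tracks the rounded
#'   cognitive-load schedule. Disable for isolated mechanics testing.
#' @return An object of class `cv_trial_config`.
#' @export
trial_config <- function(schedule,
                         seed,
                         icon_count = 16,
                         alert_types = NULL,
                         admin_thresholds = c(3, 5, 7, 9, 11),
                         ip_pool_size = 15,
                         flicker_timeout = 10,
                         breach_timeout = 15,
                         center_service_floor = 2,
                         strict_miss_rule = FALSE,
                         increment_by_rating = FALSE,
                         ai_enabled = TRUE) {
  check_schedule(schedule)
  check_number(seed, "seed", integerish = TRUE)
  check_number(icon_count, "icon_count", lower = 1, integerish = TRUE)
  check_number(ip_pool_size, "ip_pool_size", lower = 1, integerish = TRUE)
  check_number(flicker_timeout, "flicker_timeout", lower = 1e-9)
  check_number(breach_timeout, "breach_timeout", lower = 1e-9)
  check_number(center_service_floor, "center_service_floor", lower = 0)
  if (is.null(alert_types)) {
    alert_types <- tibble::tibble(
      name = c("corporate_privacy_violation", "broken_access_control",
               "sensitive_data_exposure", "unknown_traffic",
               "server_security_misconfiguration"),
      priority = 1:5
    )
  }
  alert_types <- tibble::as_tibble(alert_types)
  n_types <- nrow(alert_types)
  if (!all(c("name", "priority") %in% names(alert_types)) ||
      !identical(sort(as.integer(alert_types$priority)), seq_len(n_types))) {
    cv_abort("`alert_types` needs columns name, priority with priorities 1..n.",
             "bad_argument")
  }
  alert_types <- dplyr::arrange(alert_types, .data$priority)
  admin_thresholds <- as.integer(admin_thresholds)
  if (length(admin_thresholds) != n_types || any(admin_thresholds < 2) ||
      any(diff(admin_thresholds) <= 0)) {
    cv_abort(
      "`admin_thresholds` must give one value >= 2 per priority, strictly increasing.",
      "bad_argument"
    )
  }
  structure(
    list(
      schedule = schedule,
      seed = as.integer(seed),
      icon_count = as.integer(icon_count),
      alert_types = alert_types,
      admin_thresholds = admin_thresholds,
      ip_pool_size = as.integer(ip_pool_size),
      flicker_timeout = flicker_timeout,
      breach_timeout = breach_timeout,
      center_service_floor = center_service_floor,
      strict_miss_rule = isTRUE(strict_miss_rule),
      increment_by_rating = isTRUE(increment_by_rating),
      ai_enabled = isTRUE(ai_enabled)
    ),
    class = "cv_trial_config"
  )
}

#' @export
print.cv_trial_config <- function(x, ...) {
  cat(sprintf("<cv_trial_config> seed %d, %s schedule (%g min)\n",
              x$seed, x$schedule$mode, x$schedule$duration))
  cat(sprintf("  %d icons, %d alert types, %d IPs/chart, thresholds %s\n",
              x$icon_count, nrow(x$alert_types), x$ip_pool_size,
              paste(x$admin_thresholds, collapse = "/")))
  invisible(x)
}

check_config <- function(config) {
  if (!inherits(config, "cv_trial_config")) {
    cv_abort("`config` must be created with trial_config().", "bad_argument")
  }
  invisible(config)
}

#' IP address label for a chart column
#'
#' IPs are unique across charts: column `k` of chart `c` is `10.0.<c>.<k>`.
#'
#' @param chart Chart number (= alert priority), integer.
#' @param ip Column index within the chart, integer.
#' @return Character vector of IP strings.
#' @export
ip_string <- function(chart, ip) sprintf("10.0.%d.%d", as.integer(chart), as.integer(ip))

parse_ip <- function(ip, config) {
  m <- regmatches(ip, regexec("^10\\.0\\.([0-9]+)\\.([0-9]+)$", ip))[[1]]
  if (length(m) != 3L) cv_abort(sprintf("Unparseable IP address '%s'.", ip), "bad_argument")
  chart <- as.integer(m[2]); col <- as.integer(m[3])
  if (chart < 1 || chart > nrow(config$alert_types) ||
      col < 1 || col > config$ip_pool_size) {
    cv_abort(sprintf("IP '%s' is outside the configured pools.", ip), "bad_argument")
  }
  c(chart = chart, ip = col)
}

# ---------------------------------------------------------------------------
# Trial state: an environment mutated in place by the event-processing
# primitives below. Screens are coded 1/2/3 (left/center/right), outcomes
# 1/2/3 (hit/miss/false_alarm), signal-id namespaces 1/2/3 (L/C/B).

SCREEN_LABELS <- c("left", "center", "right")
OUTCOME_LABELS <- c("hit", "miss", "false_alarm")
ID_PREFIX <- c("L", "C", "B")

#' Create a fresh trial state
#'
#' The state tracks icon flicker status (a FIFO of active flickers, oldest
#' first), the center alert queue, every frequency-chart column count, open
#' threshold breaches, and the accumulated outcome records. It is an
#' environment: [apply_action()], [advance_time()] and [inject_stimulus()]
#' mutate it in place and return the outcome records they generated.
#'
#' If the configuration enables the built-in AI, creating the state primes the
#' charts so that the number of near-critical columns (count exactly one below
#' the chart's admin threshold) equals the rounded cognitive-load target at
#' t = 0; this consumes random draws from the current RNG state.
#'
#' @param config A [trial_config()].
#' @return An environment of class `cv_trial_state`.
#' @export
new_trial_state <- function(config) {
  check_config(config)
  S <- new.env(parent = emptyenv())
  S$cfg <- config
  S$n_types <- nrow(config$alert_types)
  S$now <- 0
  S$dur_s <- config$schedule$duration * 60
  S$finished <- FALSE

  S$flicker_active <- logical(config$icon_count)
  S$fq_t <- numeric(256); S$fq_icon <- integer(256); S$fq_id <- integer(256)
  S$fq_head <- 1L; S$fq_tail <- 0L
  S$next_left_id <- 0L
  S$dropped <- 0L

  S$aq_pri <- integer(64); S$aq_ip <- integer(64); S$aq_id <- integer(64)
  S$aq_head <- 1L; S$aq_tail <- 0L
  S$next_alert_id <- 0L

  S$counts <- matrix(0L, S$n_types, config$ip_pool_size)
  S$th <- config$admin_thresholds
  S$th_mat <- matrix(S$th, S$n_types, config$ip_pool_size)
  S$breach_open <- matrix(FALSE, S$n_types, config$ip_pool_size)
  S$breach_t <- matrix(NA_real_, S$n_types, config$ip_pool_size)
  S$breach_id <- matrix(NA_integer_, S$n_types, config$ip_pool_size)
  S$open_idx <- integer(0)
  S$next_breach_id <- 0L
  S$nc_count <- 0L

  steps <- load_target_steps(config$schedule)
  S$step_t <- steps$t * 60
  S$step_v <- as.integer(steps$target)
  S$target <- S$step_v[1]
  S$step_i <- 2L  # next pending target step

  S$o_t <- numeric(1024); S$o_screen <- integer(1024); S$o_out <- integer(1024)
  S$o_idtype <- integer(1024); S$o_idnum <- integer(1024)
  S$o_n <- 0L

  S$inj_t <- numeric(64); S$inj_chart <- integer(64); S$inj_ip <- integer(64)
  S$inj_amt <- integer(64); S$inj_nc <- integer(64)
  S$inj_n <- 0L

  if (config$ai_enabled) ai_topup(S, 0)
  class(S) <- "cv_trial_state"
  S
}

check_state <- function(state) {
  if (!inherits(state, "cv_trial_state")) {
    cv_abort("`state` must be created with new_trial_state().", "bad_argument")
  }
  if (isTRUE(state$finished)) {
    cv_abort("Trial has finished; no further events can be applied.", "state")
  }
  invisible(state)
}

out_add <- function(S, t, screen, outcome, idtype, idnum) {
  n <- S$o_n + 1L
  if (n > length(S$o_t)) {
    m <- 2L * length(S$o_t)
    length(S$o_t) <- m; length(S$o_screen) <- m; length(S$o_out) <- m
    length(S$o_idtype) <- m; length(S$o_idnum) <- m
  }
  S$o_t[n] <- t; S$o_screen[n] <- screen; S$o_out[n] <- outcome
  S$o_idtype[n] <- idtype; S$o_idnum[n] <- idnum
  S$o_n <- n
}

# Expire overdue flickers and breaches and apply cognitive-load target steps,
# in time order, up to `to`.
st_advance <- function(S, to) {
  ft <- S$cfg$flicker_timeout
  bt <- S$cfg$breach_timeout
  repeat {
    t_f <- if (S$fq_head <= S$fq_tail) S$fq_t[S$fq_head] + ft else Inf
    t_b <- if (length(S$open_idx)) min(S$breach_t[S$open_idx]) + bt else Inf
    t_s <- if (S$step_i <= length(S$step_t)) S$step_t[S$step_i] else Inf
    t_next <- min(t_f, t_b, t_s)
    if (t_next > to) break
    if (t_f <= t_b && t_f <= t_s) {
      h <- S$fq_head
      out_add(S, t_f, 1L, 2L, 1L, S$fq_id[h])
      S$flicker_active[S$fq_icon[h]] <- FALSE
      S$fq_head <- h + 1L
    } else if (t_b <= t_s) {
      which_b <- S$open_idx[which.min(S$breach_t[S$open_idx])]
      tb <- S$breach_t[which_b] + bt
      out_add(S, tb, 3L, 2L, 3L, S$breach_id[which_b])
      close_breach(S, which_b, reset = TRUE)
      if (S$cfg$ai_enabled) ai_topup(S, tb)
    } else {
      S$target <- S$step_v[S$step_i]
      tt <- S$step_t[S$step_i]
      S$step_i <- S$step_i + 1L
      if (S$cfg$ai_enabled) ai_topup(S, tt)
    }
  }
  S$now <- to
  invisible(S)
}

close_breach <- function(S, idx, reset) {
  S$breach_open[idx] <- FALSE
  S$open_idx <- S$open_idx[S$open_idx != idx]
  if (reset) {
    S$counts[idx] <- 0L
    # a reset column can itself be near-critical only if threshold - 1 == 0,
    # impossible with thresholds >= 2
  }
  S$breach_t[idx] <- NA_real_
}

# Column arithmetic shared by center ratings, AI injections and user-injected
# increments. Opens a breach when the count reaches/crosses the threshold.
increment_column <- function(S, t, chart, ip, amount, from_ai = FALSE) {
  idx <- chart + (ip - 1L) * S$n_types
  old <- S$counts[idx]
  new <- old + as.integer(amount)
  S$counts[idx] <- new
  th <- S$th[chart]
  if (!S$breach_open[idx]) {
    if (new >= th) {
      if (old == th - 1L) S$nc_count <- S$nc_count - 1L
      S$next_breach_id <- S$next_breach_id + 1L
      S$breach_open[idx] <- TRUE
      S$breach_t[idx] <- t
      S$breach_id[idx] <- S$next_breach_id
      S$open_idx <- c(S$open_idx, idx)
    } else if (new == th - 1L && old != th - 1L) {
      S$nc_count <- S$nc_count + 1L
    } else if (old == th - 1L && new != th - 1L) {
      S$nc_count <- S$nc_count - 1L
    }
  }
  if (!from_ai && S$cfg$ai_enabled) ai_topup(S, t)
  if (S$breach_open[idx] && S$breach_t[idx] == t) idx else 0L
}

# Top up near-critical columns until their number matches the current target.
# Each injection raises one random eligible column (count <= threshold - 2, no
# open breach) to exactly threshold - 1: the AI never crosses a threshold
# itself, so every breach is driven by operator rating activity.
ai_topup <- function(S, t) {
  while (S$nc_count < S$target) {
    elig <- which(S$counts <= S$th_mat - 2L & !S$breach_open)
    if (!length(elig)) break
    pick <- elig[min(length(elig), floor(stats::runif(1) * length(elig)) + 1L)]
    chart <- ((pick - 1L) %% S$n_types) + 1L
    ip <- ((pick - 1L) %/% S$n_types) + 1L
    amt <- (S$th[chart] - 1L) - S$counts[pick]
    S$counts[pick] <- S$th[chart] - 1L
    S$nc_count <- S$nc_count + 1L
    n <- S$inj_n + 1L
    if (n > length(S$inj_t)) {
      m <- 2L * length(S$inj_t)
      length(S$inj_t) <- m; length(S$inj_chart) <- m; length(S$inj_ip) <- m
      length(S$inj_amt) <- m; length(S$inj_nc) <- m
    }
    S$inj_t[n] <- t; S$inj_chart[n] <- chart; S$inj_ip[n] <- ip
    S$inj_amt[n] <- amt; S$inj_nc[n] <- S$nc_count
    S$inj_n <- n
  }
}

st_onset <- function(S, t, icon_u) {
  greens <- which(!S$flicker_active)
  if (!length(greens)) {
    S$dropped <- S$dropped + 1L
    S$next_left_id <- S$next_left_id + 1L
    return(NA_integer_)
  }
  icon <- greens[min(length(greens), floor(icon_u * length(greens)) + 1L)]
  S$next_left_id <- S$next_left_id + 1L
  n <- S$fq_tail + 1L
  if (n > length(S$fq_t)) {
    m <- 2L * length(S$fq_t)
    length(S$fq_t) <- m; length(S$fq_icon) <- m; length(S$fq_id) <- m
  }
  S$fq_t[n] <- t; S$fq_icon[n] <- icon; S$fq_id[n] <- S$next_left_id
  S$fq_tail <- n
  S$flicker_active[icon] <- TRUE
  icon
}

st_macro <- function(S, t) {
  if (S$fq_head <= S$fq_tail) {
    h <- S$fq_head
    out_add(S, t, 1L, 1L, 1L, S$fq_id[h])
    S$flicker_active[S$fq_icon[h]] <- FALSE
    S$fq_head <- h + 1L
  } else {
    out_add(S, t, 1L, 3L, 0L, 0L)
  }
}

strict_miss_check <- function(S, t) {
  if (S$cfg$strict_miss_rule && S$fq_head <= S$fq_tail) {
    out_add(S, t, 1L, 2L, 0L, 0L)
  }
}

st_alert_arrival <- function(S, ip, priority) {
  S$next_alert_id <- S$next_alert_id + 1L
  n <- S$aq_tail + 1L
  if (n > length(S$aq_pri)) {
    m <- 2L * length(S$aq_pri)
    length(S$aq_pri) <- m; length(S$aq_ip) <- m; length(S$aq_id) <- m
  }
  S$aq_pri[n] <- as.integer(priority); S$aq_ip[n] <- as.integer(ip)
  S$aq_id[n] <- S$next_alert_id
  S$aq_tail <- n
  S$next_alert_id
}

# Rate the head-of-queue alert. Returns the linear column index of a breach
# opened by the resulting chart increment, or 0.
st_rate <- function(S, t, score) {
  if (S$aq_head > S$aq_tail) {
    cv_abort("rate_alert with an empty alert queue.", "state")
  }
  strict_miss_check(S, t)
  h <- S$aq_head
  pri <- S$aq_pri[h]; ip <- S$aq_ip[h]; id <- S$aq_id[h]
  S$aq_head <- h + 1L
  outcome <- if (score == pri) 1L else if (score < pri) 3L else 2L
  out_add(S, t, 2L, outcome, 2L, id)
  chart <- if (S$cfg$increment_by_rating) as.integer(score) else pri
  increment_column(S, t, chart, ip, 1L)
}

st_admin <- function(S, t, chart, ip) {
  strict_miss_check(S, t)
  idx <- chart + (ip - 1L) * S$n_types
  if (S$breach_open[idx]) {
    out_add(S, t, 3L, 1L, 3L, S$breach_id[idx])
    close_breach(S, idx, reset = TRUE)
    if (S$cfg$ai_enabled) ai_topup(S, t)
  } else {
    out_add(S, t, 3L, 3L, 0L, 0L)
  }
}

outcomes_window <- function(S, from_n) {
  idx <- seq.int(from_n + 1L, length.out = S$o_n - from_n)
  tibble::tibble(
    timestamp_s = S$o_t[idx],
    screen = SCREEN_LABELS[S$o_screen[idx]],
    outcome = OUTCOME_LABELS[S$o_out[idx]],
    signal_id = ifelse(S$o_idtype[idx] == 0L, NA_character_,
                       paste0(ID_PREFIX[pmax(S$o_idtype[idx], 1L)], S$o_idnum[idx]))
  )
}

# ---------------------------------------------------------------------------
# Exported stepwise API

#' Apply an operator action to a trial state
#'
#' Classification rules:
#' * **left** -- a macro press with at least one active flicker scores a hit
#'   on the *oldest* active flicker (which reverts to green); with none
#'   active it is a left false alarm.
#' * **center** -- rating the head-of-queue alert with score `r` against true
#'   priority `p`: `r = p` hit; `r < p` false alarm (lower score = more severe
#'   = overestimated threat); `r > p` miss. The alert leaves the queue and the
#'   chart column for its IP (true alert type by default) increments by one.
#' * **right** -- `admin_alert(ip)` while a breach is open on that IP scores a
#'   hit and resets the column to zero; otherwise it is a right false alarm.
#'
#' Time advances to `timestamp` first, so overdue flicker/breach timeouts are
#' scored (as misses) before the action is applied.
#'
#' @param state A [new_trial_state()] environment (mutated in place).
#' @param timestamp Action time in seconds (>= current state time).
#' @param action `"macro_ctrl_d"`, `"rate_alert"` or `"admin_alert"`.
#' @param score Threat score 1..n for `rate_alert`.
#' @param ip IP string (e.g. `"10.0.3.7"`) for `admin_alert`.
#' @return Tibble of outcome records generated by the call (timeouts included).
#' @export
apply_action <- function(state, timestamp,
                         action = c("macro_ctrl_d", "rate_alert", "admin_alert"),
                         score = NULL, ip = NULL) {
  check_state(state)
  action <- match.arg(action)
  check_number(timestamp, "timestamp", lower = 0)
  if (timestamp < state$now) {
    cv_abort("`timestamp` is before the current state time.", "bad_argument")
  }
  n0 <- state$o_n
  st_advance(state, timestamp)
  if (action == "macro_ctrl_d") {
    st_macro(state, timestamp)
  } else if (action == "rate_alert") {
    if (is.null(score)) cv_abort("rate_alert needs a `score`.", "bad_argument")
    check_number(score, "score", lower = 1, upper = state$n_types, integerish = TRUE)
    st_rate(state, timestamp, as.integer(score))
  } else {
    if (is.null(ip)) cv_abort("admin_alert needs an `ip`.", "bad_argument")
    loc <- parse_ip(ip, state$cfg)
    st_admin(state, timestamp, loc[["chart"]], loc[["ip"]])
  }
  outcomes_window(state, n0)
}

#' Advance the trial clock
#'
#' Moves the state to time `to`, resolving overdue signals on the way: any
#' flicker active longer than the flicker timeout becomes a left miss (icon
#' reverts to green) and any breach open longer than the breach timeout
#' becomes a right miss (column resets). Each signal resolves exactly once.
#'
#' @param state A [new_trial_state()] environment (mutated in place).
#' @param to Target time in seconds (>= current state time).
#' @return Tibble of timeout outcome records generated by the call.
#' @export
advance_time <- function(state, to) {
  check_state(state)
  check_number(to, "to", lower = 0)
  if (to < state$now) cv_abort("`to` is before the current state time.", "bad_argument")
  n0 <- state$o_n
  st_advance(state, to)
  outcomes_window(state, n0)
}

#' Inject a stimulus event into a trial state
#'
#' Used to drive the stepwise engine API directly (e.g. in tests or custom
#' schedulers): a left-screen flicker onset, a center-screen alert arrival, or
#' a chart increment (an "AI" contribution). Unlike the built-in AI, an
#' injected increment *may* cross a chart threshold, in which case it opens a
#' breach.
#'
#' @param state A [new_trial_state()] environment (mutated in place).
#' @param timestamp Event time in seconds.
#' @param kind `"flicker_onset"`, `"alert_arrival"` or `"ai_injection"`.
#' @param icon Icon index for flicker onsets; a random green icon if `NULL`.
#' @param ip IP string identifying the alert origin / chart column.
#' @param priority True alert priority (1..n) for alert arrivals.
#' @param increment Column increment for `ai_injection` (default 1).
#' @return Tibble of outcome records generated (timeouts, possibly a breach).
#' @export
inject_stimulus <- function(state, timestamp,
                            kind = c("flicker_onset", "alert_arrival", "ai_injection"),
                            icon = NULL, ip = NULL, priority = NULL, increment = 1) {
  check_state(state)
  kind <- match.arg(kind)
  check_number(timestamp, "timestamp", lower = 0)
  if (timestamp < state$now) {
    cv_abort("`timestamp` is before the current state time.", "bad_argument")
  }
  n0 <- state$o_n
  st_advance(state, timestamp)
  if (kind == "flicker_onset") {
    if (is.null(icon)) {
      st_onset(state, timestamp, stats::runif(1))
    } else {
      check_number(icon, "icon", lower = 1, upper = state$cfg$icon_count,
                   integerish = TRUE)
      if (state$flicker_active[icon]) {
        cv_abort("Icon is already flickering.", "bad_argument")
      }
      state$next_left_id <- state$next_left_id + 1L
      n <- state$fq_tail + 1L
      if (n > length(state$fq_t)) {
        m <- 2L * length(state$fq_t)
        length(state$fq_t) <- m; length(state$fq_icon) <- m; length(state$fq_id) <- m
      }
      state$fq_t[n] <- timestamp; state$fq_icon[n] <- as.integer(icon)
      state$fq_id[n] <- state$next_left_id
      state$fq_tail <- n
      state$flicker_active[icon] <- TRUE
    }
  } else if (kind == "alert_arrival") {
    if (is.null(ip) || is.null(priority)) {
      cv_abort("alert_arrival needs `ip` and `priority`.", "bad_argument")
    }
    loc <- parse_ip(ip, state$cfg)
    check_number(priority, "priority", lower = 1, upper = state$n_types,
                 integerish = TRUE)
    st_alert_arrival(state, loc[["ip"]], priority)
  } else {
    if (is.null(ip)) cv_abort("ai_injection needs an `ip`.", "bad_argument")
    loc <- parse_ip(ip, state$cfg)
    check_number(increment, "increment", lower = 1, integerish = TRUE)
    increment_column(state, timestamp, loc[["chart"]], loc[["ip"]],
                     as.integer(increment), from_ai = TRUE)
  }
  outcomes_window(state, n0)
}

#' Inspect a trial state
#'
#' `state_outcomes()` returns all outcome records so far; `chart_counts()` the
#' current frequency-chart column counts (charts in rows, named by alert
#' priority; IP columns); `open_breaches()` the currently open threshold
#' breaches.
#'
#' @param state A `cv_trial_state`.
#' @return A tibble (or matrix for `chart_counts()`).
#' @export
state_outcomes <- function(state) {
  if (!inherits(state, "cv_trial_state")) {
    cv_abort("`state` must be a cv_trial_state.", "bad_argument")
  }
  outcomes_window(state, 0L)
}

#' @rdname state_outcomes
#' @export
chart_counts <- function(state) {
  if (!inherits(state, "cv_trial_state")) {
    cv_abort("`state` must be a cv_trial_state.", "bad_argument")
  }
  m <- state$counts
  dimnames(m) <- list(priority = seq_len(state$n_types),
                      ip = seq_len(state$cfg$ip_pool_size))
  m
}

#' @rdname state_outcomes
#' @export
open_breaches <- function(state) {
  if (!inherits(state, "cv_trial_state")) {
    cv_abort("`state` must be a cv_trial_state.", "bad_argument")
  }
  idx <- state$open_idx
  chart <- ((idx - 1L) %% state$n_types) + 1L
  ip <- ((idx - 1L) %/% state$n_types) + 1L
  tibble::tibble(
    chart = chart, ip = ip_string(chart, ip),
    opened_s = state$breach_t[idx],
    signal_id = paste0("B", state$breach_id[idx])
  )
}
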