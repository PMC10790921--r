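# Shared fixtures and independent oracles.

quick_config <- function(mode = "static", duration = 6, seed = 1, ...) {
  trial_config(workload_schedule(mode, duration = duration), seed = seed, ...)
}

# pure-mechanics config: no AI top-ups interfering with hand-built states
mech_config <- function(mode = "static", duration = 6, seed = 1, ...) {
  quick_config(mode, duration, seed, ai_enabled = FALSE, ...)
}

perfect_operator <- function() {
  operator_params(
    base_detect = c(left = 1, center = 1, right = 1),
    salience_coeff = 0, rate_coeff = 0, load_coeff = 0,
    learn_coeff = 0, fatigue_coeff = 0,
    false_alarm_rate = c(left = 0, center = 0, right = 0),
    latency_meanlog = log(0.5), latency_sdlog = 0.1,
    clamp = c(0, 1)
  )
}

inert_operator <- function() {
  operator_params(
    base_detect = c(left = 0, center = 0, right = 0),
    salience_coeff = 0, rate_coeff = 0, load_coeff = 0,
    learn_coeff = 0, fatigue_coeff = 0,
    false_alarm_rate = c(left = 0, center = 0, right = 0),
    clamp = c(0, 1)
  )
}

# O(n^2) brute-force Mann-Kendall S over explicit pairs
mk_brute_s <- function(x) {
  x <- x[!is.na(x)]
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

# brute-force Sen slope: enumerate pairwise slopes at original positions
sen_brute <- function(x) {
  pos <- which(!is.na(x))
  v <- x[pos]
  slopes <- c()
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slopes <- c(slopes, (v[j] - v[i]) / (pos[j] - pos[i]))
    }
  }
  stats::median(slopes)
}

# minimal hand-built trial log for scoring tests
fake_log <- function(outcomes, duration = 6, mode = "static") {
  structure(
    list(
      config = quick_config(mode, duration = duration),
      operator = operator_params(),
      operator_seed = 1L,
      stimuli = tibble::tibble(),
      actions = tibble::tibble(),
      outcomes = outcomes,
      dropped_onsets = 0L
    ),
    class = "cv_trial_log"
  )
}

# Independent replay of the right-screen chart dynamics from a trial log.
# Rebuilds every column count from the logged center ratings (paired in FIFO
# order with the alert arrivals), AI injections and breach outcomes, and
# checks: (a) a column never sits above its threshold without an open breach,
# (b) breaches open in the engine exactly when the replay crosses a
# threshold, (c) after the final AI injection of each timestamp burst the
# near-critical column count equals the rounded cognitive-load target.
replay_charts <- function(log) {
  cfg <- log$config
  n_types <- nrow(cfg$alert_types)
  th <- cfg$admin_thresholds
  dur <- cfg$schedule$duration

  arrivals <- log$stimuli[log$stimuli$kind == "alert_arrival", ]
  ratings <- log$actions[log$actions$action == "rate_alert", ]
  stopifnot(nrow(arrivals) == nrow(ratings))
  loc <- function(ipstr) {
    p <- as.integer(strsplit(ipstr, ".", fixed = TRUE)[[1]][3:4])
    p
  }
  arr_loc <- t(vapply(arrivals$ip, loc, integer(2)))
  inc_chart <- if (cfg$increment_by_rating) ratings$score else arrivals$priority
  injections <- log$stimuli[log$stimuli$kind == "ai_injection", ]
  inj_loc <- t(vapply(injections$ip, loc, integer(2)))

  breach_out <- log$outcomes[log$outcomes$screen == "right" &
                               !is.na(log$outcomes$signal_id), ]
  breach_out <- breach_out[order(as.integer(sub("^B", "", breach_out$signal_id))), ]

  # merged replay events: increments (ratings), injections, breach resets
  ev <- dplyr::bind_rows(
    tibble::tibble(t = ratings$timestamp_s, kind = 1L,
                   chart = inc_chart, ip = arr_loc[, 2], amt = 1L),
    tibble::tibble(t = injections$timestamp_s, kind = 2L,
                   chart = injections$chart, ip = inj_loc[, 2],
                   amt = injections$increment),
    tibble::tibble(t = breach_out$timestamp_s, kind = 0L,
                   chart = NA_integer_, ip = NA_integer_,
                   amt = as.integer(sub("^B", "", breach_out$signal_id)))
  )
  # resets/increments before the reactive AI injections on timestamp ties
  ev <- ev[order(ev$t, ev$kind), ]

  counts <- matrix(0L, n_types, cfg$ip_pool_size)
  open <- matrix(FALSE, n_types, cfg$ip_pool_size)
  breach_col <- list()  # breach id -> c(chart, ip)
  n_breach <- 0L
  nc_count <- function() sum(counts == matrix(th, n_types, cfg$ip_pool_size) - 1L & !open)
  target_at <- function(t_s) floor(cognitive_load_at(cfg$schedule, min(t_s / 60, dur)) + 0.5)

  ok_threshold <- TRUE
  ok_nc <- TRUE
  for (r in seq_len(nrow(ev))) {
    k <- ev$kind[r]
    if (k == 0L) {  # breach resolution: column resets
      cc <- breach_col[[ev$amt[r]]]
      counts[cc[1], cc[2]] <- 0L
      open[cc[1], cc[2]] <- FALSE
    } else {
      ch <- ev$chart[r]; ip <- ev$ip[r]
      counts[ch, ip] <- counts[ch, ip] + ev$amt[r]
      if (!open[ch, ip] && counts[ch, ip] >= th[ch]) {
        n_breach <- n_breach + 1L
        breach_col[[n_breach]] <- c(ch, ip)
        open[ch, ip] <- TRUE
      }
    }
    if (any(counts > matrix(th, n_types, cfg$ip_pool_size) & !open)) {
      ok_threshold <- FALSE
    }
    is_last_inj_of_burst <- k == 2L &&
      (r == nrow(ev) || ev$kind[r + 1L] != 2L || ev$t[r + 1L] != ev$t[r])
    if (is_last_inj_of_burst && nc_count() != target_at(ev$t[r])) {
      ok_nc <- FALSE
    }
  }
  list(
    ok_threshold = ok_threshold,
    ok_nc = ok_nc,
    n_breach_replayed = n_breach,
    n_breach_logged = nrow(breach_out)
  )
}
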