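#' Define a neurocognitive workload schedule
#'
#' A workload schedule parameterizes the three task-difficulty factors over a
#' trial: signal salience \eqn{S(t)} (honeyfile-icon flicker frequency, Hz;
#' detection is *harder* at higher frequencies, approaching the perceptual
#' limit at 48 Hz), background event rate \eqn{E(t)} (critical left-screen
#' signals per minute) and cognitive load \eqn{C_{load}(t)} (the number of
#' near-critical chart columns the operator must hold in working memory).
#'
#' In `"dynamic"` mode each factor ramps linearly from the easy bound at
#' `t = 0` to the hard bound at `t = duration` (with the defaults this gives
#' the slopes 7/15 Hz/min, 2/15 events/min\eqn{^2} and 1/20 columns/min).
#' In `"static"` mode every factor is held constant at its most difficult
#' processing value, i.e. the upper bound of each pair, for the whole trial.
#'
#' @param mode `"dynamic"` or `"static"`.
#' @param duration Trial length in minutes (default 60).
#' @param salience_bounds Flicker-frequency bounds in Hz, default `c(20, 48)`,
#'   the band within which attention to flickering signals is optimized.
#' @param event_rate_bounds Critical-signal rate bounds in events/min,
#'   default `c(8, 16)`.
#' @param load_bounds Near-critical signal count bounds, default `c(1, 4)`
#'   (working-memory limited: five alert priorities are already retained).
#' @return An object of class `cv_schedule`.
#' @seealso [salience_at()], [event_rate_at()], [cognitive_load_at()],
#'   [workload_at()]
#' @examples
#' sch <- workload_schedule("dynamic")
#' salience_at(sch, c(0, 30, 60))
#' workload_at(sch, 0)
#' @export
workload_schedule <- function(mode = c("dynamic", "static"),
                              duration = 60,
                              salience_bounds = c(20, 48),
                              event_rate_bounds = c(8, 16),
                              load_bounds = c(1, 4)) {
  mode <- match.arg(mode)
  check_number(duration, "duration", lower = 1e-9)
  check_bounds_pair(salience_bounds, "salience_bounds")
  check_bounds_pair(event_rate_bounds, "event_rate_bounds")
  check_bounds_pair(load_bounds, "load_bounds")
  structure(
    list(
      mode = mode,
      duration = duration,
      salience_bounds = as.numeric(salience_bounds),
      event_rate_bounds = as.numeric(event_rate_bounds),
      load_bounds = as.numeric(load_bounds)
    ),
    class = "cv_schedule"
  )
}

#' @export
print.cv_schedule <- function(x, ...) {
  cat(sprintf("<cv_schedule> %s, %g min\n", x$mode, x$duration))
  cat(sprintf("  salience  : %g-%g Hz\n", x$salience_bounds[1], x$salience_bounds[2]))
  cat(sprintf("  event rate: %g-%g events/min\n",
              x$event_rate_bounds[1], x$event_rate_bounds[2]))
  cat(sprintf("  cog. load : %g-%g near-critical columns\n",
              x$load_bounds[1], x$load_bounds[2]))
  invisible(x)
}

check_schedule <- function(schedule) {
  if (!inherits(schedule, "cv_schedule")) {
    cv_abort("`schedule` must be created with workload_schedule().", "bad_argument")
  }
  invisible(schedule)
}

check_time <- function(schedule, t) {
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t))) {
    cv_abort("`t` must be finite numeric minutes.", "bad_argument")
  }
  if (any(t < 0 | t > schedule$duration)) {
    cv_abort(
      sprintf("`t` must lie within [0, %g] minutes.", schedule$duration),
      "domain"
    )
  }
  invisible(t)
}

sched_component <- function(schedule, t, bounds) {
  check_schedule(schedule)
  check_time(schedule, t)
  if (schedule$mode == "static") {
    rep(bounds[2], length(t))
  } else {
    bounds[1] + (bounds[2] - bounds[1]) / schedule$duration * t
  }
}

#' Workload components at a time point
#'
#' Evaluate the scheduled signal salience, event rate or cognitive load at
#' trial time `t` (minutes). All three are vectorized over `t`; times outside
#' `[0, duration]` raise a domain error. Cognitive load is returned as the
#' continuous scheduled value; the task engine materializes it to an integer
#' target by rounding half up.
#'
#' @param schedule A [workload_schedule()].
#' @param t Time(s) in minutes since trial start.
#' @return Numeric vector: Hz for `salience_at()`, events/min for
#'   `event_rate_at()`, a (continuous) near-critical column count for
#'   `cognitive_load_at()`.
#' @examples
#' dyn <- workload_schedule("dynamic")
#' salience_at(dyn, 30)        # 34 Hz, midpoint of the 20-48 ramp
#' event_rate_at(dyn, 60)      # 16 events/min
#' cognitive_load_at(dyn, 20)  # 2 near-critical columns
#' @export
salience_at <- function(schedule, t) {
  sched_component(schedule, t, schedule$salience_bounds)
}

#' @rdname salience_at
#' @export
event_rate_at <- function(schedule, t) {
  sched_component(schedule, t, schedule$event_rate_bounds)
}

#' @rdname salience_at
#' @export
cognitive_load_at <- function(schedule, t) {
  sched_component(schedule, t, schedule$load_bounds)
}

#' Workload vector at a time point
#'
#' The full workload vector \eqn{\tilde{w}(t) = [S(t), E(t), C_{load}(t)]}
#' as a tibble, one row per requested time.
#'
#' @inheritParams salience_at
#' @return A tibble with columns `t`, `salience_hz`, `event_rate`,
#'   `cognitive_load`.
#' @examples
#' workload_at(workload_schedule("static"), c(0, 30, 60))
#' @export
workload_at <- function(schedule, t) {
  tibble::tibble(
    t = t,
    salience_hz = salience_at(schedule, t),
    event_rate = event_rate_at(schedule, t),
    cognitive_load = cognitive_load_at(schedule, t)
  )
}

# Normalized (0-1) workload components; shared by the operator model.
# Each component maps its bounds pair onto [0, 1], so in static mode all are 1
# and in dynamic mode all equal t/duration (linear ramps between the bounds).
norm_workload_at <- function(schedule, t) {
  nb <- function(x, b) (x - b[1]) / (b[2] - b[1])
  tibble::tibble(
    t = t,
    salience = nb(salience_at(schedule, t), schedule$salience_bounds),
    event_rate = nb(event_rate_at(schedule, t), schedule$event_rate_bounds),
    load = nb(cognitive_load_at(schedule, t), schedule$load_bounds)
  )
}

# Cumulative normalized workload in "hours at full load":
# W(t) = (1/60) * integral_0^t mean-normalized-workload(u) du, with t in
# minutes. Static: t/60. Dynamic: t^2 / (120 * duration).
cumulative_workload_at <- function(schedule, t) {
  check_schedule(schedule)
  check_time(schedule, t)
  if (schedule$mode == "static") t / 60 else t^2 / (120 * schedule$duration)
}

# Times (minutes) at which the integer cognitive-load target changes, plus the
# target value from each time onward. Half-up rounding means the target steps
# at load value k - 0.5.
load_target_steps <- function(schedule) {
  lo <- schedule$load_bounds[1]
  hi <- schedule$load_bounds[2]
  t0 <- round_half_up(cognitive_load_at(schedule, 0))
  if (schedule$mode == "static") {
    return(tibble::tibble(t = 0, target = round_half_up(hi)))
  }
  slope <- (hi - lo) / schedule$duration
  targets <- seq(t0, round_half_up(hi))
  t_change <- c(0, (targets[-1] - 0.5 - lo) / slope)
  tibble::tibble(t = t_change, target = targets)
}
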