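# JSON Lines trial-log serialization and run-configuration parsing.

CV_SCHEMA_VERSION <- 1L

config_to_list <- function(config) {
  list(
    schedule = list(
      mode = config$schedule$mode,
      duration = config$schedule$duration,
      salience_bounds = config$schedule$salience_bounds,
      event_rate_bounds = config$schedule$event_rate_bounds,
      load_bounds = config$schedule$load_bounds
    ),
    seed = config$seed,
    icon_count = config$icon_count,
    alert_types = list(name = config$alert_types$name,
                       priority = config$alert_types$priority),
    admin_thresholds = config$admin_thresholds,
    ip_pool_size = config$ip_pool_size,
    flicker_timeout = config$flicker_timeout,
    breach_timeout = config$breach_timeout,
    center_service_floor = config$center_service_floor,
    strict_miss_rule = config$strict_miss_rule,
    increment_by_rating = config$increment_by_rating,
    ai_enabled = config$ai_enabled
  )
}

config_from_list <- function(x) {
  trial_config(
    schedule = workload_schedule(
      mode = x$schedule$mode,
      duration = x$schedule$duration,
      salience_bounds = unlist(x$schedule$salience_bounds),
      event_rate_bounds = unlist(x$schedule$event_rate_bounds),
      load_bounds = unlist(x$schedule$load_bounds)
    ),
    seed = x$seed,
    icon_count = x$icon_count,
    alert_types = tibble::tibble(name = unlist(x$alert_types$name),
                                 priority = unlist(x$alert_types$priority)),
    admin_thresholds = unlist(x$admin_thresholds),
    ip_pool_size = x$ip_pool_size,
    flicker_timeout = x$flicker_timeout,
    breach_timeout = x$breach_timeout,
    center_service_floor = x$center_service_floor,
    strict_miss_rule = x$strict_miss_rule,
    increment_by_rating = x$increment_by_rating,
    ai_enabled = x$ai_enabled
  )
}

operator_to_list <- function(op) {
  list(
    base_detect = as.list(op$base_detect),
    salience_coeff = op$salience_coeff, rate_coeff = op$rate_coeff,
    load_coeff = op$load_coeff, learn_coeff = op$learn_coeff,
    fatigue_coeff = op$fatigue_coeff,
    false_alarm_rate = as.list(op$false_alarm_rate),
    latency_meanlog = op$latency_meanlog, latency_sdlog = op$latency_sdlog,
    service_meanlog = op$service_meanlog, service_sdlog = op$service_sdlog,
    clamp = op$clamp
  )
}

operator_from_list <- function(x) {
  operator_params(
    base_detect = unlist(x$base_detect),
    salience_coeff = x$salience_coeff, rate_coeff = x$rate_coeff,
    load_coeff = x$load_coeff, learn_coeff = x$learn_coeff,
    fatigue_coeff = x$fatigue_coeff,
    false_alarm_rate = unlist(x$false_alarm_rate),
    latency_meanlog = x$latency_meanlog, latency_sdlog = x$latency_sdlog,
    service_meanlog = x$service_meanlog, service_sdlog = x$service_sdlog,
    clamp = unlist(x$clamp)
  )
}

log_event_frame <- function(log) {
  stim <- dplyr::mutate(log$stimuli, record_type = "stimulus")
  acts <- dplyr::mutate(log$actions, record_type = "action")
  outs <- dplyr::mutate(log$outcomes, record_type = "outcome")
  dplyr::bind_rows(stim, acts, outs)
}

#' Write / read a trial log as JSON Lines
#'
#' One JSON object per line: a header line carrying the schema version, the
#' full trial and operator configuration, the seeds and a configuration hash,
#' followed by every stimulus, action and outcome record (`record_type`
#' distinguishes them). The round trip is lossless; the reader validates the
#' schema version and that timestamps are non-decreasing within each record
#' type, and reports the offending line number otherwise.
#'
#' @param log A `cv_trial_log`.
#' @param path File path.
#' @return `write_trial_log()`: `path`, invisibly. `read_trial_log()`: the
#'   reconstructed `cv_trial_log`.
#' @export
write_trial_log <- function(log, path) {
  check_trial_log(log)
  header <- list(
    record_type = "header",
    schema_version = CV_SCHEMA_VERSION,
    config = config_to_list(log$config),
    operator = operator_to_list(log$operator),
    operator_seed = log$operator_seed,
    dropped_onsets = log$dropped_onsets
  )
  header$config_hash <- rlang::hash(header[c("config", "operator", "operator_seed")])
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  jsonlite::stream_out(log_event_frame(log), con, verbose = FALSE,
                       digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) cv_abort("Empty file: missing header line.", "parse")
  valid <- vapply(lines, jsonlite::validate, logical(1), USE.NAMES = FALSE)
  if (!all(valid)) {
    cv_abort(sprintf("Malformed JSON at line %d.", which(!valid)[1]), "parse")
  }
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$record_type, "header")) {
    cv_abort("Missing header: line 1 is not a header record.", "parse")
  }
  if (!identical(as.integer(header$schema_version), CV_SCHEMA_VERSION)) {
    cv_abort(sprintf("Schema version mismatch at line 1 (got %s).",
                     header$schema_version), "parse")
  }
  if (length(lines) > 1) {
    body <- jsonlite::stream_in(textConnection(lines[-1]), verbose = FALSE)
  } else {
    body <- data.frame()
  }
  if (nrow(body) && (!"record_type" %in% names(body) ||
                     !"timestamp_s" %in% names(body))) {
    cv_abort("Event records must carry record_type and timestamp_s.", "parse")
  }
  for (rt in c("stimulus", "action", "outcome")) {
    rows <- which(body$record_type == rt)
    ts <- body$timestamp_s[rows]
    bad <- which(diff(ts) < 0)
    if (length(bad)) {
      cv_abort(sprintf("Non-monotone %s timestamps at line %d.",
                       rt, rows[bad[1] + 1L] + 1L), "parse")
    }
  }

  grab <- function(rt, cols) {
    d <- body[body$record_type == rt, intersect(cols, names(body)), drop = FALSE]
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    tibble::as_tibble(d[cols])
  }
  stim <- grab("stimulus", c("timestamp_s", "screen", "kind", "icon",
                             "flicker_hz", "ip", "priority", "chart",
                             "increment", "signal_id"))
  stim$icon <- as.integer(stim$icon)
  stim$priority <- as.integer(stim$priority)
  stim$chart <- as.integer(stim$chart)
  stim$increment <- as.integer(stim$increment)
  stim$flicker_hz <- as.numeric(stim$flicker_hz)
  stim$ip <- as.character(stim$ip)
  stim$signal_id <- as.character(stim$signal_id)
  acts <- grab("action", c("timestamp_s", "action", "score", "ip"))
  acts$score <- as.integer(acts$score)
  acts$ip <- as.character(acts$ip)
  outs <- grab("outcome", c("timestamp_s", "screen", "outcome", "signal_id"))
  outs$signal_id <- as.character(outs$signal_id)

  structure(
    list(
      config = config_from_list(header$config),
      operator = operator_from_list(header$operator),
      operator_seed = as.integer(header$operator_seed),
      stimuli = stim,
      actions = acts,
      outcomes = outs,
      dropped_onsets = as.integer(header$dropped_onsets)
    ),
    class = "cv_trial_log"
  )
}

#' Read a run configuration (JSON)
#'
#' A run configuration bundles the trial options, the operator parameter
#' sections for the static and dynamic conditions, and the cohort size and
#' base seed. Example:
#' ```json
#' {
#'   "trial": {"duration": 60},
#'   "operator": {"static": {}, "dynamic": {}},
#'   "cohort": {"n": 25, "base_seed": 1}
#' }
#' ```
#' Omitted fields fall back to package defaults; operator sections accept any
#' [operator_params()] argument.
#'
#' @param path JSON file path.
#' @return A list of class `cv_run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cohort <- x$cohort %||% list()
  n <- cohort$n %||% 25L
  base_seed <- cohort$base_seed %||% 1L
  check_number(n, "cohort$n", lower = 2, integerish = TRUE)
  check_number(base_seed, "cohort$base_seed", integerish = TRUE)
  op_of <- function(section) {
    args <- x$operator[[section]] %||% list()
    if (length(args)) do.call(operator_params, lapply(args, unlist)) else operator_params()
  }
  structure(
    list(
      trial = as.list(x$trial %||% list()),
      operator_static = op_of("static"),
      operator_dynamic = op_of("dynamic"),
      n = as.integer(n),
      base_seed = as.integer(base_seed)
    ),
    class = "cv_run_config"
  )
}
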