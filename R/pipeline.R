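# End-to-end pipeline helpers behind the command-line surface: simulate a
# cohort to disk, analyze a directory of logs, and recompute the analytic
# self-checks.

#' Simulate a cohort and write it to a directory
#'
#' Runs [simulate_cohort()] from a run configuration and writes one JSON Lines
#' log per trial plus a `manifest.json` listing every file with its seeds,
#' order label and content hash. Reruns with the same configuration produce
#' byte-identical logs and an identical manifest hash.
#'
#' @param run_config A [read_run_config()] object (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
simulate_to_dir <- function(run_config, out_dir) {
  if (is.character(run_config)) run_config <- read_run_config(run_config)
  if (!inherits(run_config, "cv_run_config")) {
    cv_abort("`run_config` must come from read_run_config().", "bad_argument")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- run_config$trial
  duration <- trial$duration %||% 60
  opts <- trial[setdiff(names(trial), "duration")]
  coh <- simulate_cohort(
    n = run_config$n,
    params_static = run_config$operator_static,
    params_dynamic = run_config$operator_dynamic,
    base_seed = run_config$base_seed,
    duration = duration,
    trial_options = opts
  )
  manifest <- coh$manifest
  manifest$file <- sprintf("p%02d_%s.jsonl", manifest$participant, manifest$mode)
  for (i in seq_len(nrow(manifest))) {
    write_trial_log(coh$logs[[i]], file.path(out_dir, manifest$file[i]))
  }
  manifest$content_hash <- vapply(
    file.path(out_dir, manifest$file),
    function(p) rlang::hash(readLines(p, warn = FALSE)),
    character(1), USE.NAMES = FALSE
  )
  jsonlite::write_json(
    list(base_seed = run_config$base_seed, n = run_config$n, files = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Analyze a directory of trial logs
#'
#' Reads every `*.jsonl` trial log, computes per-trial and ensemble vigilance
#' curves for each condition, the publication-shaped trend report and (for
#' 60-minute trials) the split-half reliability coefficients, and writes them
#' as CSV/TSV/JSON into `out_dir`. Needs at least two logs per condition for
#' ensemble statistics.
#'
#' @param in_dir Directory containing trial logs written by
#'   [simulate_to_dir()] / [write_trial_log()].
#' @param out_dir Output directory (created if needed).
#' @param width Bucket width in minutes (default 2).
#' @param plots If `TRUE`, also writes vigilance-performance-curve figures.
#' @return List with `ensembles`, `report`, `split_half`, invisibly.
#' @export
analyze_dir <- function(in_dir, out_dir, width = 2, plots = FALSE) {
  files <- list.files(in_dir, pattern = "\\.jsonl$", full.names = TRUE)
  if (!length(files)) cv_abort("No .jsonl trial logs found.", "bad_argument")
  logs <- lapply(files, read_trial_log)
  modes <- vapply(logs, function(l) l$config$schedule$mode, character(1))
  if (any(!table(factor(modes, levels = c("static", "dynamic"))) >= 2)) {
    cv_abort("Need at least two logs per condition for ensemble statistics.",
             "bad_argument")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- lapply(logs, vigilance_curve, width = width)
  for (i in seq_along(curves)) {
    write_curve_csv(curves[[i]],
                    file.path(out_dir, sub("\\.jsonl$", "_curve.csv",
                                           basename(files[i]))))
  }
  ens <- list(
    static = ensemble_average(curves[modes == "static"]),
    dynamic = ensemble_average(curves[modes == "dynamic"])
  )
  write_curve_csv(ens$static, file.path(out_dir, "ensemble_static.csv"))
  write_curve_csv(ens$dynamic, file.path(out_dir, "ensemble_dynamic.csv"))
  report <- trend_report(ens$static, ens$dynamic)
  write_trend_report(report, file.path(out_dir, "trend_report.tsv"))
  jsonlite::write_json(tibble::as_tibble(report),
                       file.path(out_dir, "trend_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  split_half <- NULL
  if (abs(logs[[1]]$config$schedule$duration - 60) < 1e-9) {
    mins <- lapply(logs, minute_detection_series)
    ens_minute <- function(mode) {
      mat <- vapply(mins[modes == mode], function(m) m$perf, numeric(60))
      rowMeans(matrix(mat, nrow = 60), na.rm = TRUE)
    }
    split_half <- purrr::map_dbl(
      c(static = "static", dynamic = "dynamic"),
      function(m) {
        s <- ens_minute(m)
        tryCatch(split_half_reliability(s), error = function(e) NA_real_)
      }
    )
    jsonlite::write_json(as.list(split_half),
                         file.path(out_dir, "split_half.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (isTRUE(plots)) {
    p <- plot_vigilance_curves(ens$static, ens$dynamic)
    ggplot2::ggsave(file.path(out_dir, "vpc_total.png"), p,
                    width = 7, height = 4.5, dpi = 150)
  }
  invisible(list(ensembles = ens, report = report, split_half = split_half))
}

#' Recompute the analytic self-checks
#'
#' Recomputes, from the package's own functions, every quantity of the task
#' design that is fixed by computation alone, and compares it against its
#' reference value: the Mann-Kendall null standard error for a 30-bucket
#' series, continuity-corrected Z statistics recovered from published S
#' statistics, the Durbin-Watson 5% bounds for n = 30, the dynamic schedule
#' endpoints, the static schedule constants, and the priority-to-threshold
#' map.
#'
#' @return Tibble with columns `check`, `value`, `expected`, `pass`.
#' @examples
#' verify_analytics()
#' @export
verify_analytics <- function() {
  checks <- list()
  add <- function(check, value, expected, tol = 5e-4) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, value = value, expected = expected,
      pass = abs(value - expected) <= tol
    )
  }

  x <- seq_len(30) + rep(c(0.25, -0.25), 15)  # untied 30-value series
  mk30 <- mann_kendall(x)
  add("mann_kendall_se_n30", mk30$se, 56.051)

  z_from_s <- function(s, se) if (s > 0) (s - 1) / se else (s + 1) / se
  add("z_from_S_-407", z_from_s(-407, mk30$se), -7.243)
  add("z_from_S_339", z_from_s(339, mk30$se), 6.030)
  add("z_from_S_303", z_from_s(303, mk30$se), 5.388)

  bd <- dw_bounds(30)
  add("dw_lower_n30", bd[["d_lower"]], 1.352)
  add("dw_upper_n30", bd[["d_upper"]], 1.489)

  dyn <- workload_schedule("dynamic")
  add("dynamic_salience_t60_hz", salience_at(dyn, 60), 48, tol = 1e-9)
  add("dynamic_event_rate_t60", event_rate_at(dyn, 60), 16, tol = 1e-9)
  add("dynamic_load_t60", cognitive_load_at(dyn, 60), 4, tol = 1e-9)
  sta <- workload_schedule("static")
  add("static_salience_hz", salience_at(sta, 17.3), 48, tol = 1e-9)
  add("static_event_rate", event_rate_at(sta, 17.3), 16, tol = 1e-9)
  add("static_load", cognitive_load_at(sta, 17.3), 4, tol = 1e-9)

  cfg <- trial_config(dyn, seed = 1)
  for (p in 1:5) {
    add(sprintf("admin_threshold_priority_%d", p),
        cfg$admin_thresholds[p], c(3, 5, 7, 9, 11)[p], tol = 0)
  }
  dplyr::bind_rows(checks)
}
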