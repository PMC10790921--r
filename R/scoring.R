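#' Bucket outcome counts
#'
#' Counts hits, misses and false alarms per screen within consecutive
#' half-open time buckets `[t, t + width)` minutes. Outcomes generated during
#' the post-trial run-out (signals still pending when the presentation window
#' closes) are clamped into the final bucket.
#'
#' @param log A [run_trial()] log.
#' @param width Bucket width in minutes (default 2); must divide the trial
#'   duration.
#' @return A tibble with one row per bucket x screen: `bucket` (0-based),
#'   `start_min`, `screen`, `hits`, `misses`, `false_alarms`.
#' @export
bucket_counts <- function(log, width = 2) {
  check_trial_log(log)
  check_number(width, "width", lower = 1e-9)
  dur <- log$config$schedule$duration
  if (abs(dur / width - round(dur / width)) > 1e-9) {
    cv_abort(sprintf("`width` (%g) must divide the trial duration (%g min).",
                     width, dur), "bad_argument")
  }
  nb <- as.integer(round(dur / width))
  o <- log$outcomes
  b <- pmin(floor(o$timestamp_s / (width * 60)), nb - 1L)
  scr <- match(o$screen, SCREEN_LABELS)
  out <- match(o$outcome, OUTCOME_LABELS)
  idx <- b * 9L + (scr - 1L) * 3L + out
  counts <- tabulate(idx, nbins = nb * 9L)
  arr <- array(counts, c(3L, 3L, nb))  # outcome x screen x bucket
  res <- tibble::tibble(
    bucket = rep(0:(nb - 1L), each = 3L),
    start_min = .data$bucket * width,
    screen = rep(SCREEN_LABELS, nb),
    hits = as.vector(arr[1L, , ]),
    misses = as.vector(arr[2L, , ]),
    false_alarms = as.vector(arr[3L, , ])
  )
  attr(res, "width") <- width
  attr(res, "duration") <- dur
  class(res) <- c("cv_bucket_counts", class(res))
  res
}

check_trial_log <- function(log) {
  if (!inherits(log, "cv_trial_log")) {
    cv_abort("`log` must be a cv_trial_log from run_trial() or read_trial_log().",
             "bad_argument")
  }
  invisible(log)
}

#' Detection-percentage vigilance curves
#'
#' Converts bucketed counts into the per-bucket correct-detection percentage
#' for each screen, \eqn{100 H / (H + M + F)}, and the pooled total-task
#' percentage \eqn{100 (H_L + H_C + H_R) / \sum (H + M + F)} (a single pooled
#' ratio over all nine counts, *not* the mean of the three screen
#' percentages). Buckets with a zero denominator are `NA`.
#'
#' @param counts A [bucket_counts()] tibble.
#' @return A `cv_curve` tibble: `bucket`, `start_min`, `perf_left`,
#'   `perf_center`, `perf_right`, `perf_total`.
#' @export
detection_percentages <- function(counts) {
  if (!inherits(counts, "cv_bucket_counts")) {
    cv_abort("`counts` must come from bucket_counts().", "bad_argument")
  }
  counts <- dplyr::arrange(counts, .data$bucket, match(.data$screen, SCREEN_LABELS))
  nb <- length(unique(counts$bucket))
  h <- matrix(counts$hits, 3L)      # screen x bucket
  m <- matrix(counts$misses, 3L)
  f <- matrix(counts$false_alarms, 3L)
  den <- h + m + f
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  res <- tibble::tibble(
    bucket = sort(unique(counts$bucket)),
    start_min = .data$bucket * attr(counts, "width"),
    perf_left = pct(h[1L, ], den[1L, ]),
    perf_center = pct(h[2L, ], den[2L, ]),
    perf_right = pct(h[3L, ], den[3L, ]),
    perf_total = pct(colSums(h), colSums(den))
  )
  attr(res, "width") <- attr(counts, "width")
  attr(res, "duration") <- attr(counts, "duration")
  class(res) <- c("cv_curve", class(res))
  res
}

#' Vigilance performance curve of a trial
#'
#' Convenience wrapper: [bucket_counts()] then [detection_percentages()].
#'
#' @inheritParams bucket_counts
#' @return A `cv_curve` tibble, see [detection_percentages()].
#' @examples
#' cfg <- trial_config(workload_schedule("static", duration = 4), seed = 1)
#' vigilance_curve(run_trial(cfg, operator_params(), 2), width = 2)
#' @export
vigilance_curve <- function(log, width = 2) {
  detection_percentages(bucket_counts(log, width))
}

#' Minute-by-minute pooled detection series
#'
#' The pooled (all-screens) detection percentage at one-minute resolution,
#' the series underlying the split-half reliability analysis. Requires a
#' 60-minute trial.
#'
#' @param log A [run_trial()] log.
#' @return A tibble `minute` (0-59), `perf` (percentage or `NA`).
#' @export
minute_detection_series <- function(log) {
  check_trial_log(log)
  if (abs(log$config$schedule$duration - 60) > 1e-9) {
    cv_abort("Minute-level series is defined for 60-minute trials.", "bad_argument")
  }
  cur <- vigilance_curve(log, width = 1)
  tibble::tibble(minute = cur$bucket, perf = cur$perf_total)
}

#' Ensemble-average vigilance curve over a cohort
#'
#' Per-bucket arithmetic mean of the detection percentages over a set of
#' curves with identical bucket structure (`NA` buckets excluded pairwise),
#' plus the per-bucket standard deviation for error bars.
#'
#' @param curves List of `cv_curve` tibbles (e.g. from [vigilance_curve()]).
#' @return A `cv_curve` tibble with the mean `perf_*` columns and companion
#'   `perf_*_sd` columns; attribute `n_curves`.
#' @export
ensemble_average <- function(curves) {
  if (inherits(curves, "cv_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "cv_curve"))) {
    cv_abort("`curves` must be a list of cv_curve objects.", "bad_argument")
  }
  nb <- nrow(curves[[1]])
  w <- attr(curves[[1]], "width")
  same <- vapply(curves, function(cc) {
    nrow(cc) == nb && isTRUE(all.equal(attr(cc, "width"), w))
  }, logical(1))
  if (!all(same)) {
    cv_abort("All curves must share the same bucket structure.", "bad_argument")
  }
  cols <- c("perf_left", "perf_center", "perf_right", "perf_total")
  res <- tibble::tibble(bucket = curves[[1]]$bucket,
                        start_min = curves[[1]]$start_min)
  for (cl in cols) {
    mat <- vapply(curves, function(cc) cc[[cl]], numeric(nb))
    mat <- matrix(mat, nrow = nb)
    res[[cl]] <- rowMeans(mat, na.rm = TRUE)
    res[[cl]][is.nan(res[[cl]])] <- NA_real_
    res[[paste0(cl, "_sd")]] <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  }
  attr(res, "width") <- w
  attr(res, "duration") <- attr(curves[[1]], "duration")
  attr(res, "n_curves") <- length(curves)
  class(res) <- c("cv_curve", class(res))
  res
}

#' Write a vigilance curve to CSV
#'
#' @param curve A `cv_curve` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}
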