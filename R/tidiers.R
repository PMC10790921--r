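# broom-style tidiers for the analysis objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the trend-analysis objects
#'
#' One-row tibbles for [mann_kendall()], [sens_slope()] and [durbin_watson()]
#' results, and the 8-row mode-by-screen tibble for [trend_report()].
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name cybervig-tidiers
NULL

#' @rdname cybervig-tidiers
#' @export
tidy.cv_mk <- function(x, ...) {
  tibble::tibble(
    statistic = x$S, var_s = x$var_S, std_error = x$se, z = x$Z,
    p_value = x$p_value, direction = x$direction, n = x$n
  )
}

#' @rdname cybervig-tidiers
#' @export
glance.cv_mk <- function(x, ...) tidy.cv_mk(x)

#' @rdname cybervig-tidiers
#' @export
tidy.cv_sen <- function(x, ...) {
  tibble::tibble(
    estimate = x$slope, conf_low = x$ci_lower, conf_high = x$ci_upper,
    conf_level = x$conf_level, n_pairs = x$n_pairs
  )
}

#' @rdname cybervig-tidiers
#' @export
tidy.cv_dw <- function(x, ...) {
  tibble::tibble(
    statistic = x$D, d_lower = x$d_lower, d_upper = x$d_upper,
    verdict = x$verdict, du_rule_significant = x$du_rule_significant, n = x$n
  )
}

#' @rdname cybervig-tidiers
#' @export
tidy.cv_trend_report <- function(x, ...) tibble::as_tibble(x)
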