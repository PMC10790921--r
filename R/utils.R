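# Internal helpers shared across modules.

# Round half away from zero for positive x ("round half up"): 1.5 -> 2, 2.5 -> 3.
# Used when materializing the continuous cognitive-load schedule to an integer
# target count; base round() would round 1.5 and 2.5 both to 2.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cv_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("cybervig_", class), "cybervig_error"), ...)
}

# scalar checks; all abort with class "cybervig_bad_argument"
check_number <- function(x, name, lower = -Inf, upper = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    cv_abort(sprintf("`%s` must be a single finite number.", name), "bad_argument")
  }
  if (x < lower || x > upper) {
    cv_abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper), "bad_argument")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    cv_abort(sprintf("`%s` must be an integer.", name), "bad_argument")
  }
  invisible(x)
}

check_bounds_pair <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] >= x[2]) {
    cv_abort(sprintf("`%s` must be a (min, max) pair with min < max.", name),
             "bad_argument")
  }
  invisible(x)
}

# Poisson stream of event times on [0, t_end) at constant rate (events per sec).
poisson_times <- function(rate_per_s, t_end) {
  if (rate_per_s <= 0 || t_end <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate_per_s * t_end)
  sort(stats::runif(n, 0, t_end))
}
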