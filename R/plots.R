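# ggplot2 figures for vigilance performance curves.

curve_long <- function(curve, label) {
  cols <- c("perf_left", "perf_center", "perf_right", "perf_total")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(curve)[c("bucket", "start_min", cols)],
    dplyr::all_of(cols),
    names_to = "screen", names_prefix = "perf_", values_to = "perf"
  )
  sds <- paste0(cols, "_sd")
  if (all(sds %in% names(curve))) {
    sd_long <- tidyr::pivot_longer(
      tibble::as_tibble(curve)[c("bucket", sds)],
      dplyr::all_of(sds),
      names_to = "screen", values_to = "sd"
    )
    sd_long$screen <- sub("^perf_(.*)_sd$", "\\1", sd_long$screen)
    long <- dplyr::left_join(long, sd_long, by = c("bucket", "screen"))
  } else {
    long$sd <- NA_real_
  }
  long$condition <- label
  long
}

#' Plot vigilance performance curves
#'
#' Detection percentage against time on task for one screen (or the pooled
#' total), static condition in red and dynamic in black, with vertical error
#' bars (one standard deviation) when the curves are ensemble averages.
#'
#' @param static,dynamic `cv_curve` tibbles (either may be `NULL`).
#' @param screen `"total"`, `"left"`, `"center"` or `"right"`.
#' @return A ggplot object.
#' @export
plot_vigilance_curves <- function(static = NULL, dynamic = NULL,
                                  screen = c("total", "left", "center", "right")) {
  screen <- match.arg(screen)
  if (is.null(static) && is.null(dynamic)) {
    cv_abort("Provide at least one curve.", "bad_argument")
  }
  dat <- dplyr::bind_rows(
    if (!is.null(static)) curve_long(static, "static"),
    if (!is.null(dynamic)) curve_long(dynamic, "dynamic")
  )
  dat <- dat[dat$screen == screen, ]
  w <- attr(static %||% dynamic, "width") %||% 2
  dat$mid_min <- dat$start_min + w / 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid_min, y = .data$perf,
                                    colour = .data$condition)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$perf - .data$sd, ymax = .data$perf + .data$sd),
      width = w / 3, na.rm = TRUE, linewidth = 0.3
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1.4) +
    ggplot2::scale_colour_manual(values = c(static = "red3", dynamic = "black")) +
    ggplot2::labs(
      x = "Time on task (min)",
      y = "Correct detection (%)",
      colour = NULL,
      title = sprintf("Vigilance performance (%s)",
                      ifelse(screen == "total", "all screens", screen))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Panel plot of a vigilance curve
#'
#' All four detection-percentage series (left, center, right, pooled total)
#' of a single curve, faceted by screen.
#'
#' @param object A `cv_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_curve <- function(object, ...) {
  dat <- curve_long(object, "trial")
  w <- attr(object, "width") %||% 2
  dat$mid_min <- dat$start_min + w / 2
  dat$screen <- factor(dat$screen, levels = c("total", "left", "center", "right"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid_min, y = .data$perf)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$screen)) +
    ggplot2::labs(x = "Time on task (min)", y = "Correct detection (%)") +
    ggplot2::theme_minimal()
}
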