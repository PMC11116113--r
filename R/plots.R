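#' @importFrom ggplot2 autoplot
NULL

#' Plot the trajectories of a trackset
#'
#' @param object a `trackset`.
#' @param ... unused.
#' @return a ggplot of the arena with one path per individual.
#' @export
autoplot.trackset <- function(object, ...) {
  a <- arena(object)
  object |>
    dplyr::filter(.data$valid) |>
    ggplot2::ggplot(ggplot2::aes(.data$x_mm, .data$y_mm,
                                 colour = .data$individual_id)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_fixed(xlim = c(0, a$width_mm), ylim = c(0, a$height_mm)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "individual") +
    ggplot2::theme_minimal()
}

#' Plot a smooth group time-course with its pointwise band
#'
#' @param object a `smooth_fit`.
#' @param level pointwise confidence level.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.smooth_fit <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$hour, .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - z * .data$se,
                                      ymax = .data$estimate + z * .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hour", y = "fitted response") +
    ggplot2::theme_minimal()
}

#' Plot a difference curve, shading significant timepoints
#'
#' The difference-plot display: the smooth group contrast with its
#' pointwise interval; hours whose interval excludes zero are marked.
#'
#' @param object a `difference_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.difference_curve <- function(object, ...) {
  groups <- attr(object, "groups")
  ggplot2::ggplot(object, ggplot2::aes(.data$hour, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = function(d) d[d$significant, ],
                        colour = "red", size = 0.8) +
    ggplot2::labs(x = "hour",
                  y = sprintf("%s - %s", groups[1], groups[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.difference_curve
#' @export
autoplot.contrast_fit <- function(object, ...) {
  autoplot(object$curve, ...)
}
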