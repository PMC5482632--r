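#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rank-based expression curve
#'
#' Smoothed sample-proportion curves over the rank-score axis, one line
#' per condition; a right-shifted peak indicates high expression.
#'
#' @param object An [rbe_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbe_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$score, y = .data$smoothed, colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "rank score", y = "sample proportion",
                  title = attr(object, "gene"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(
    x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey60") +
    ggplot2::geom_path(colour = "firebrick", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC %.3f (%.3f-%.3f)", object$auc,
                                     object$conf_low, object$conf_high)) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier fit
#'
#' @param object A [km_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  steps <- dplyr::bind_rows(
    tibble(time = 0, estimate = 1, conf_low = 1, conf_high = 1),
    object$steps)
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_step(colour = "steelblue", linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since remission", y = "relapse-free survival") +
    ggplot2::theme_minimal()
}

#' Plot cumulative incidence functions
#'
#' @param object A [cif_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cif_fit <- function(object, ...) {
  steps <- dplyr::bind_rows(
    tidyr::expand_grid(cause = unique(object$steps$cause),
                       time = 0, estimate = 0),
    object$steps[c("cause", "time", "estimate")])
  ggplot2::ggplot(steps, ggplot2::aes(
    x = .data$time, y = .data$estimate, colour = .data$cause)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since remission", y = "cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
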