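#' Plot resubstitution accuracy curves
#'
#' Line plot of mean resubstitution accuracy against sample size, one
#' panel per target correlation and one colour per predictor count, with
#' the chance level at 0.5 marked.
#'
#' @param object An `"accuracy_curves"` tibble from [run_study1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$mean_accuracy,
                               colour = factor(.data$p))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$r),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n", y = "mean accuracy",
                  colour = "predictors p") +
    ggplot2::theme_minimal()
}

#' Plot estimator-minus-test difference curves with the stability corridor
#'
#' Line plot of the per-n mean accuracy difference (estimator minus
#' independent-test accuracy) per scheme, with dashed horizontal lines at
#' the corridor boundaries and, when a stability result is supplied,
#' vertical lines at each scheme's point of stability.
#'
#' @param object A `"difference_curves"` tibble from [run_study2()].
#' @param half_width Corridor half-width drawn as dashed boundaries.
#'   Default 0.05.
#' @param stability Optional result of [point_of_stability()]; reached
#'   points of stability are drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.difference_curves <- function(object, half_width = 0.05,
                                       stability = NULL, ...) {
  pl <- ggplot2::ggplot(object,
                        ggplot2::aes(x = .data$n, y = .data$mean_diff,
                                     colour = .data$scheme)) +
    ggplot2::geom_hline(yintercept = c(-half_width, half_width),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample size n",
                  y = "accuracy difference (estimate - test set)",
                  colour = "scheme") +
    ggplot2::theme_minimal()
  if (!is.null(stability)) {
    hits <- dplyr::filter(stability, .data$reached)
    if (nrow(hits) > 0L) {
      pl <- pl + ggplot2::geom_vline(
        data = hits,
        ggplot2::aes(xintercept = .data$pos_n, colour = .data$scheme),
        linetype = "longdash", show.legend = FALSE)
    }
  }
  pl
}

#' Plot an accuracy audit
#'
#' Dot-and-interval plot of the audited accuracies with their exact
#' binomial confidence intervals and the chance level at 50%.
#'
#' @param object An `"accuracy_audit"` tibble from [audit_accuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_audit <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scheme, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
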