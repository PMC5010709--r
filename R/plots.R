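## ggplot2 displays for the main result objects

#' Plot the composition of final models across methods
#'
#' Bars of the average percentage of biologically relevant variables per
#' method, with per-replicate points overlaid.
#'
#' @param object a `bag_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bag_experiment
#' @export
autoplot.bag_experiment <- function(object, ...) {
  reps <- object$replicates
  reps$method <- factor(reps$method, levels = c("baseline", "B1", "B2", "B3"))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$method,
                                     y = .data$pct_relevant)) +
    ggplot2::stat_summary(fun = mean, geom = "col", width = 0.7,
                          fill = "grey70") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "% biologically relevant in final model") +
    ggplot2::theme_minimal()
}

#' Plot prediction-error ratios across methods
#'
#' @param x a `bag_experiment`.
#' @param ... unused.
#' @return A ggplot object showing per-replicate PRPMSE by method with the
#'   no-change line at 100.
#' @export
plot_prpmse <- function(x, ...) {
  stopifnot(inherits(x, "bag_experiment"))
  reps <- dplyr::filter(x$replicates, .data$method != "baseline")
  reps$method <- factor(reps$method, levels = c("B1", "B2", "B3"))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$method, y = .data$prpmse)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "red3") +
    ggplot2::labs(x = NULL, y = "PRPMSE (%)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Percentage of relevant variables against bag size, one line per method,
#' faceted by B2 threshold.
#'
#' @param object a `bag_sweep` from [sensitivity_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bag_sweep
#' @export
autoplot.bag_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$q,
                               y = .data$pct_relevant_of_stage1,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$threshold),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bag size q",
                  y = "% biologically relevant (of stage-1 size)") +
    ggplot2::theme_minimal()
}
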