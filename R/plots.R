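# ggplot2 views of the package's result objects.

#' Plot a fusion-coefficient sweep
#'
#' Accuracy versus fusion coefficient, one line per classifier.
#'
#' @param object a `wgdipc_sweep` from [alpha_sweep()].
#' @param metric column to plot (`"acc"` or `"mcc"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wgdipc_sweep <- function(object, metric = "acc", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$alpha, y = .data[[metric]],
                               colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fusion coefficient α (weight of DipC)",
                  y = toupper(metric), colour = "classifier") +
    ggplot2::theme_minimal()
}

#' Plot a selection result
#'
#' Feature scores in rank order, with the selected set highlighted.
#'
#' @param object a `wgdipc_selection`.
#' @param top show only the first `top` ranks.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wgdipc_selection <- function(object, top = 50L, ...) {
  tb <- dplyr::slice_min(tidy(object), .data$rank, n = top)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste0(object$method, " feature scores"),
                  x = "rank", y = "score") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metrics per fold
#'
#' @param object a `wgdipc_cv`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wgdipc_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0,
                         ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = NULL, y = "value", colour = "fold",
                  title = paste0(object$classifier,
                                 if (!is.null(object$selector))
                                   paste0(" + ", object$selector) else "",
                                 ", ", object$folds, "-fold CV")) +
    ggplot2::theme_minimal()
}
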