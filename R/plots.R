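#' Plot gate retention trajectories
#'
#' One line per view: retention probability over training epochs, with the
#' selection threshold as a dashed line. Views converging above the
#' threshold are the ones the deterministic mask retains.
#'
#' @param object An `sv_history` or `sv_fusion_fit`.
#' @param threshold Selection threshold to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sv_history <- function(object, threshold = 0.5, ...) {
  df <- gate_trajectories(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch,
                                   y = .data$retention_probability,
                                   colour = .data$view_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "retention probability P(z > 0)",
                  colour = "view") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sv_history
#' @export
autoplot.sv_fusion_fit <- function(object, threshold = 0.5, ...) {
  autoplot.sv_history(object$history, threshold = threshold, ...)
}

#' Plot the accuracy/FLOPs trade-off of a sweep
#'
#' All sweep records as points (labelled by configuration), with the Pareto
#' frontier as a step line and the recommended configuration highlighted.
#'
#' @param object A [sweep_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_table <- function(object, ...) {
  tab <- tibble::as_tibble(object)[!is.na(object$accuracy), ]
  if (!"configuration" %in% names(tab)) {
    tab$configuration <- label_configurations(object)$configuration
  }
  fr <- pareto_frontier(tab)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$flops, y = .data$accuracy)) +
    ggplot2::geom_step(data = fr, direction = "hv", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$configuration),
                        size = 3) +
    ggplot2::geom_point(
      data = tab[tab$configuration == "recommended", , drop = FALSE],
      shape = 8, size = 5) +
    ggplot2::labs(x = "FLOPs (G)", y = "Top-1 accuracy (%)",
                  colour = "configuration") +
    ggplot2::theme_minimal()
}

#' Plot per-view single-view accuracies
#'
#' @param object An `sv_single_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sv_single_fit <- function(object, ...) {
  tab <- object$accuracy_table
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$view_name,
                                                       .data$accuracy),
                                    y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Top-1 accuracy (%)") +
    ggplot2::theme_minimal()
}
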