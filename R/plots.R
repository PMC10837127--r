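#' Plot the cell-type composition of a selection
#'
#' Bar chart of ground-truth type counts among selected cells — the
#' quickest way to see whether a strategy balanced rare types.
#'
#' @param selection A `cellpick_selection` (or data frame with `cell_id`).
#' @param truth Ground-truth labels.
#' @return A ggplot object.
#' @export
plot_selection_composition <- function(selection, truth) {
  lk <- label_lookup(truth)
  df <- tibble(cell_type = unname(lk[selection$cell_id]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "selected cells",
                  title = unique(selection$strategy)[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.novel_type_report <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$cell_type, y = .data$scaled_entropy,
                               fill = .data$cell_type == object$held_out_type)) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "purple3",
                                          `FALSE` = "goldenrod2")) +
    ggplot2::labs(x = NULL, y = "scaled entropy",
                  title = sprintf("'%s' x%d in initial set (%s)",
                                  object$held_out_type, object$n_copies,
                                  object$model_kind)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.cellpick_benchmark <- function(object, metric = "balanced_accuracy",
                                        ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$strategy,
                                                  -.data[[metric]],
                                                  FUN = stats::median),
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.5) +
    ggplot2::facet_wrap(~budget, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the per-iteration accuracy trace of an active-learning run
#'
#' @param run An `al_run` from [active_learning_loop()] (with an
#'   evaluation set supplied, so the trace holds accuracies).
#' @return A ggplot object.
#' @export
plot_al_trace <- function(run) {
  ggplot2::ggplot(run$trace,
                  ggplot2::aes(x = .data$n_labeled, y = .data$accuracy)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "labeled cells", y = "held-out accuracy") +
    ggplot2::theme_minimal()
}
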