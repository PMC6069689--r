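# ggplot2 displays for the result types.

#' Plot a precision-recall curve
#'
#' @param object A `ppi_pr_curve` tibble from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object (step curve of precision against recall).
#' @export
autoplot.ppi_pr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("PR curve (%d reference positives, AUC %.3f)",
                                  attr(object, "n_positive"), pr_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot per-method F-measures
#'
#' @param object A `ppi_evaluation` tibble from [evaluate_methods()].
#' @param ... Unused.
#' @return A ggplot object: F-measure per method, one panel per path level.
#' @export
autoplot.ppi_evaluation <- function(object, ...) {
  df <- as_tibble(object)
  df$method <- factor(df$method, levels = ppi_methods()$method)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$f_measure)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "F-measure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the consensus-score distribution of an ensemble
#'
#' @param ens A `ppi_ensemble` tibble.
#' @return A ggplot bar chart of edge counts per consensus score.
#' @export
plot_ensemble_support <- function(ens) {
  df <- dplyr::count(as_tibble(ens), .data$score)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$score), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Consensus score (fraction of best methods)", y = "Edges") +
    ggplot2::theme_minimal()
}
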