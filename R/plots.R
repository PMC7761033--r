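# ggplot2 views of the main result types

#' Plot cross-validation accuracy across the configuration grid
#'
#' Accuracy by gene-set level, one line per algorithm, faceted by slack
#' margin.
#'
#' @param grid A `"miniabs_grid"` tibble from [run_grid()].
#' @return A ggplot object.
#' @export
plot_grid_accuracy <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$level, y = .data$cv_accuracy,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "gene-set level", y = "CV accuracy",
                  colour = "algorithm") +
    ggplot2::theme_minimal()
}

#' @method autoplot miniabs_grid
#' @export
autoplot.miniabs_grid <- function(object, ...) plot_grid_accuracy(object)

#' @method autoplot miniabs_importance
#' @export
autoplot.miniabs_importance <- function(object, ...) {
  genes <- object$genes
  ggplot2::ggplot(genes, ggplot2::aes(x = stats::reorder(.data$gene,
                                                         .data$importance),
                                      y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean decrease in Gini (summed over pairs)") +
    ggplot2::theme_minimal()
}

#' @method autoplot miniabs_reduction
#' @export
autoplot.miniabs_reduction <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$n_genes,
                                            y = .data$cv_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "genes retained", y = "CV accuracy",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @method autoplot miniabs_eval
#' @export
autoplot.miniabs_eval <- function(object, ...) {
  conf <- tidy(object)
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b") +
    ggplot2::labs(x = "reference subtype", y = "predicted subtype",
                  fill = "samples") +
    ggplot2::theme_minimal()
}
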