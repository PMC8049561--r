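#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot admixture weights of a qpAdm fit
#'
#' Bar plot of the estimated weights with one-standard-error bars.
#'
#' @param object A `qpadm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qpadm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$weight - .data$se,
                                        ymax = .data$weight + .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(y = "admixture weight", x = "source",
                  title = sprintf("target %s  (P = %.3g)", object$target,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Histogram of model P-values
#'
#' @param p_values Numeric vector of P-values.
#' @param bins Number of bins.
#' @return A ggplot object with the 0.05 plausibility threshold marked.
#' @export
plot_pvalue_hist <- function(p_values, bins = 20) {
  ggplot2::ggplot(tibble::tibble(p = p_values), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(x = "P-value", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Heatmap of a plausibility matrix
#'
#' @param matrix_tbl Tibble from [plausibility_matrix()] (or the `matrix`
#'   element of [experiment_model_comparison()]) with columns `sources` and
#'   `prop_plausible` (optionally `protocol` for faceting).
#' @return A ggplot object.
#' @export
plot_plausibility_heatmap <- function(matrix_tbl) {
  d <- matrix_tbl |>
    tidyr::separate_wider_delim("sources", "+", names = c("source_1", "source_2"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$source_1, y = .data$source_2,
                                       fill = .data$prop_plausible)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop_plausible)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "source 1", y = "source 2", fill = "plausible") +
    ggplot2::theme_minimal()
  if ("protocol" %in% names(matrix_tbl)) {
    p <- p + ggplot2::facet_wrap(~protocol)
  }
  p
}

#' Scatter plot of the first two principal components
#'
#' @param pca Tibble from [pca_projection()].
#' @return A ggplot object.
#' @export
plot_pca <- function(pca) {
  ggplot2::ggplot(pca, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "population") +
    ggplot2::theme_minimal()
}

#' Estimated versus simulated admixture proportions
#'
#' @param accuracy Tibble from [experiment_alpha_accuracy()].
#' @return A ggplot object.
#' @export
plot_alpha_accuracy <- function(accuracy) {
  ggplot2::ggplot(accuracy, ggplot2::aes(x = factor(.data$alpha),
                                         y = .data$alpha_hat)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$alpha), colour = "firebrick",
                        shape = 4, size = 2) +
    ggplot2::labs(x = "simulated admixture proportion",
                  y = "estimated admixture proportion") +
    ggplot2::theme_minimal()
}
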