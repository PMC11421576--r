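#' Plot a window statistic along the genome
#'
#' @param window_tbl tibble with `chrom`, `start` and the statistic column.
#' @param stat name of the statistic column.
#' @param colour optional grouping column (e.g. `species`).
#' @return a ggplot object.
#' @export
plot_window_stat <- function(window_tbl, stat, colour = NULL) {
  p <- ggplot2::ggplot(window_tbl,
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data[[stat]]))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]),
                                na.rm = TRUE)
  } else {
    p <- p + ggplot2::geom_line(na.rm = TRUE)
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree and loading plot for a landscape PCA
#'
#' @param object a [summarize_pca()] result.
#' @param ... unused.
#' @return a ggplot object showing per-unit PC1 loadings with the PC1
#'   variance share in the title.
#' @export
autoplot.landscape_pca <- function(object, ...) {
  ggplot2::ggplot(object$loadings,
                  ggplot2::aes(x = stats::reorder(.data$unit, .data$pc1),
                               y = .data$pc1)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "PC1 loading",
      title = sprintf("PC1 explains %.1f%% of variance",
                      100 * object$var_explained[1])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of f-branch values
#'
#' @param fb tibble from [f_branch()].
#' @return a ggplot object (branches x donor species).
#' @export
plot_fbranch <- function(fb) {
  ggplot2::ggplot(fb, ggplot2::aes(x = .data$donor, y = .data$branch,
                                   fill = .data$fb)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "donor species", y = "recipient branch",
                  fill = "f-branch") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Windowed fdM scan plot with called regions highlighted
#'
#' @param calls output of [call_regions()].
#' @return a ggplot object.
#' @export
plot_fdm_calls <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$start / 1e6, y = .data$fdm)) +
    ggplot2::geom_line(colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(calls, .data$called),
                        colour = "red", size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "fdM") +
    ggplot2::theme_minimal()
}
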