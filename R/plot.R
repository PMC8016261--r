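#' Notched-box summary of per-cell enrichment by group
#'
#' Mirrors the standard presentation of per-cell z-score populations:
#' notched boxes (median and its confidence notch, box from the 25th to
#' 75th percentile) with the per-cell points overlaid.
#'
#' @param scores Data frame of per-cell scores (as from [score_cells()]).
#' @param group_col,value_col Grouping and value columns.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(scores, group_col = "construct",
                            value_col = "z") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    xs_parameter_error("plot_enrichment requires the ggplot2 package")
  ggplot2::ggplot(scores, ggplot2::aes(
      x = .data[[group_col]], y = .data[[value_col]],
      fill = .data[[group_col]])) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Enrichment z-score") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_classic()
}
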