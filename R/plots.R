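# ggplot2 views of the main result types.

#' Plot windowed statistics along chromosomes
#'
#' @param stats window-statistic tibble (from [pi_windows()],
#'   [fst_windows()], [hapdiv_windows()] or `recomb_windows()$windows`),
#'   optionally several bound together.
#' @param highlight optional tibble (`chromosome`, `start`, `end`) of spans
#'   to shade (e.g. inversion spans).
#' @return a ggplot object.
#' @export
plot_window_stats <- function(stats, highlight = NULL) {
  p <- ggplot2::ggplot(stats, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(statistic ~ chromosome, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(highlight))
    p <- p + ggplot2::geom_rect(
      data = highlight,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange",
      inherit.aes = FALSE)
  p
}

#' Plot rearranged regions along the reference
#'
#' @param regions merged region tibble ([merge_rearranged()]).
#' @return a ggplot object.
#' @export
plot_rearrangements <- function(regions) {
  ggplot2::ggplot(regions, ggplot2::aes(
    xmin = .data$ref_start / 1e6, xmax = .data$ref_end / 1e6,
    ymin = 0, ymax = 1, fill = .data$kind)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(ref_chrom ~ .) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "reference position (Mb)", y = NULL, fill = "kind") +
    ggplot2::theme_minimal()
}

#' Plot a TE divergence landscape
#'
#' @param landscape result of [divergence_landscape()].
#' @return a ggplot object.
#' @export
plot_divergence_landscape <- function(landscape) {
  h <- landscape$histogram
  h <- h[is.finite(h$bin_low), , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_low, y = .data$percent)) +
    ggplot2::geom_col(width = min(h$bin_high - h$bin_low)) +
    ggplot2::labs(x = "K2P divergence", y = "% of TE bp") +
    ggplot2::theme_minimal()
}
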