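#' Plot a repeat landscape
#'
#' Genome fraction per divergence bin, filled by family — the classic
#' repeat-landscape view of a TE family's activity through time (low
#' divergence = recent activity).
#'
#' @param object A `te_landscape` from [landscape()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_landscape <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                   y = .data$fraction, fill = .data$family)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9) +
    ggplot2::labs(x = "Jukes-Cantor divergence to consensus",
                  y = "Genome fraction", fill = "Family") +
    ggplot2::theme_minimal()
}

#' Plot homology blocks along a locus
#'
#' Draws the block segmentation of [segment_blocks()] as labelled segments
#' coloured by exact per-block identity.
#'
#' @param blocks A blocks tibble from [segment_blocks()].
#' @return A ggplot.
#' @export
plot_blocks <- function(blocks) {
  ggplot2::ggplot(blocks,
                  ggplot2::aes(x = .data$locus_start, xend = .data$locus_end,
                               y = 1, yend = 1, colour = .data$identity)) +
    ggplot2::geom_segment(linewidth = 6) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$locus_start + .data$locus_end) / 2, y = 1.15,
      label = sprintf("%s (%.1f%%)", .data$label, 100 * .data$identity)),
      size = 3, colour = "black") +
    ggplot2::scale_colour_gradient(low = "grey70", high = "firebrick",
                                   limits = c(0, 1)) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0.8, 1.3)) +
    ggplot2::labs(x = "Locus position (bp)", colour = "Identity") +
    ggplot2::theme_minimal()
}
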