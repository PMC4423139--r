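#' Plot a repeat architecture as a segment diagram
#'
#' One horizontal track per protein: grey terminal segments, repeat units
#' colored by type label, linkers hatched dark. Mirrors the vertical-line
#' segmentation style used for published EDCRP alignments.
#'
#' @param object A `repeat_architecture` from [decompose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repeat_architecture <- function(object, ...) {
  segs <- tidy(object, segments = TRUE)
  segs$fill <- ifelse(segs$segment == "unit", segs$type_label, segs$segment)
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1,
                                    fill = .data$fill),
                       color = "grey20", linewidth = 0.2) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "residue (0-based)", y = NULL, fill = "segment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of CC-dipeptide spacings
#'
#' Shades the expected 8-11 residue periodicity band.
#'
#' @param x A `cc_periodicity` object or a protein sequence string.
#' @param band Spacing band to highlight (taken from the object when given).
#' @return A ggplot object.
#' @export
plot_cc_spacings <- function(x, band = c(8L, 11L)) {
  if (is.character(x)) x <- cc_periodicity(x, band = band)
  band <- x$band
  df <- tibble(spacing = x$spacings)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spacing)) +
    ggplot2::annotate("rect", xmin = band[1] - 0.5, xmax = band[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "CC site spacing (residues)", y = "count") +
    ggplot2::theme_minimal()
}
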