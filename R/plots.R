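#' Plot blacklist regions along the genome
#'
#' One horizontal track per chromosome; regions drawn as coloured segments
#' by label.
#'
#' @param object A `blacklist_regions` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blacklist_regions
#' @export
autoplot.blacklist_regions <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                                       y = .data$chrom, yend = .data$chrom,
                                       colour = .data$name),
                          linewidth = 4) +
    ggplot2::labs(x = "position (kb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-bin standard signal tracks
#'
#' Read-depth and multimapping standard values along each chromosome, with
#' called regions (if given) shaded underneath.  Useful to see why a region
#' was (or was not) called.
#'
#' @param object A `normalized_signal` tibble.
#' @param regions Optional `blacklist_regions` to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot normalized_signal
#' @export
autoplot.normalized_signal <- function(object, regions = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble(chrom = object$chrom, start = object$start,
           `reads / mappable base` = object$depth_std,
           `multimapping / million` = object$multi_std),
    cols = c("reads / mappable base", "multimapping / million"),
    names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long)
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_step(ggplot2::aes(x = .data$start / 1e3, y = .data$value),
                       colour = "steelblue") +
    ggplot2::facet_grid(metric ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (kb)", y = "standard value (median across samples)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
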