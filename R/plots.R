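#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' LOD-curve plot of a genome scan
#'
#' @param object A `"pedscan_scan"` tibble (with map annotation).
#' @param threshold Optional genome-wide LOD threshold drawn as a dashed
#'   line.
#' @param ... Unused.
#' @return A ggplot object, faceted by chromosome.
#' @export
autoplot.pedscan_scan <- function(object, threshold = NULL, ...) {
  dat <- dplyr::filter(object, .data$testable)
  if (all(is.na(dat$chr))) {
    dat$chr <- "genome"
    dat$pos <- seq_len(nrow(dat))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Histogram of a genome-wide max-statistic distribution
#'
#' @param object A `"maxdist"` object.
#' @param q Quantile marked with a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maxdist <- function(object, q = 0.95, ...) {
  ggplot2::ggplot(
    tibble::tibble(max_lrt = object$samples),
    ggplot2::aes(x = .data$max_lrt)
  ) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = quantile.maxdist(object, q),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "genome-wide max LRT",
      title = paste0(object$method, " null distribution")
    ) +
    ggplot2::theme_minimal()
}
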