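#' Plot a genome-wide LOD profile
#'
#' One panel per chromosome, LOD against physical position (Mb), with an
#' optional threshold line and peak markers, in the style of the standard
#' linkage-mapping figure.
#'
#' @param object A `qtl_scan` tibble.
#' @param threshold Optional LOD threshold to draw (defaults to the scan's
#'   recorded threshold, if any).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_scan <- function(object, threshold = attr(object, "threshold"),
                              ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$lod,
                                    colour = .data$trait)) +
    ggplot2::geom_line(show.legend = length(unique(object$trait)) > 1) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Genomic position (Mb)", y = "LOD") +
    ggplot2::theme_bw()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  pk <- attr(object, "peaks")
  if (!is.null(pk) && nrow(pk) > 0) {
    p <- p + ggplot2::geom_point(
      data = pk, ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$lod),
      colour = "red", shape = 17, inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot.qtl_scan
#' @export
plot_scan <- function(object, ...) autoplot.qtl_scan(object, ...)

#' Plot an FDR curve
#'
#' Observed and expected peak counts against the candidate LOD threshold,
#' with the selected threshold marked.
#'
#' @param object An `fdr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("observed", "expected"),
                              names_to = "which", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$count,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "LOD threshold", y = "Peaks",
                  title = sprintf("Selected threshold: LOD %.2f",
                                  object$threshold)) +
    ggplot2::theme_bw()
}

#' Plot sorter events coloured by object class
#'
#' TOF against EXT; bubbles, which are optically thin for their size, fall on
#' a shallower slope than animals.
#'
#' @param events Event tibble with an `object_class` or `truth` column.
#' @return A ggplot object.
#' @export
plot_events <- function(events) {
  cls <- if ("object_class" %in% names(events)) "object_class" else "truth"
  ggplot2::ggplot(events, ggplot2::aes(x = .data$TOF, y = .data$EXT,
                                       colour = .data[[cls]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "TOF (length)", y = "EXT (optical density)") +
    ggplot2::theme_bw()
}
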