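#' Plot a log2-ratio track with its segmentation
#'
#' Probe log2 ratios along the genome, faceted by chromosome, with segment
#' means overlaid as horizontal bars and the calling thresholds as dashed
#' lines.
#'
#' @param track A log2-ratio track from [to_log2_track()].
#' @param segmentation Optional `cgh_segmentation` from [segment_track()].
#' @param threshold Calling threshold drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_track <- function(track, segmentation = NULL, threshold = 0.5) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$midpoint / 1e6,
                                    y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "log2(test / reference)") +
    ggplot2::theme_bw()
  if (!is.null(segmentation)) {
    segs <- if (inherits(segmentation, "cgh_segmentation")) {
      segmentation$segments
    } else {
      segmentation
    }
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "dodgerblue3", linewidth = 1
    )
  }
  p
}

#' @rdname plot_track
#' @param object A `cgh_segmentation`; requires the `track` it was fitted on.
#' @param ... Passed on to [plot_track()].
#' @exportS3Method ggplot2::autoplot
autoplot.cgh_segmentation <- function(object, track, ...) {
  plot_track(track, segmentation = object, ...)
}

#' Bar chart of the CNVR size distribution
#'
#' @param cnvrs A CNVR tibble (or the output of [size_bins()]).
#' @return A ggplot object.
#' @export
plot_size_bins <- function(cnvrs) {
  bins <- if (all(c("bin", "n") %in% names(cnvrs))) cnvrs else size_bins(cnvrs)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "CNVR size", y = "Count") +
    ggplot2::theme_bw()
}

#' Per-chromosome CNVR coverage plot
#'
#' @param chrom_summary Output of [chromosome_summary()]; the `Total` row is
#'   dropped.
#' @return A ggplot object.
#' @export
plot_chromosome_summary <- function(chrom_summary) {
  d <- chrom_summary |> filter(.data$chrom != "Total")
  d$chrom <- factor(d$chrom, levels = d$chrom)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom, y = .data$pct_of_chrom)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "Chromosome", y = "CNVR coverage (% of chromosome)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
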