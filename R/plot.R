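#' Plot a coverage track with optional intron hints
#'
#' @param coverage Coverage tibble (`scaffold`, `pos`, `depth`).
#' @param intron_hints Optional hint tibble drawn as segments under the
#'   track.
#' @param scaffold Restrict to one scaffold (default: all, faceted).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, intron_hints = NULL, scaffold = NULL) {
  cov <- coverage
  if (!is.null(scaffold)) {
    cov <- cov |> filter(.data$scaffold == !!scaffold)
  }
  p <- ggplot2::ggplot(cov, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.8) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x", ncol = 1L) +
    ggplot2::labs(x = "position (0-based)", y = "depth") +
    ggplot2::theme_minimal()
  if (!is.null(intron_hints) && nrow(intron_hints)) {
    h <- intron_hints
    if (!is.null(scaffold)) h <- h |> filter(.data$scaffold == !!scaffold)
    p <- p + ggplot2::geom_segment(
      data = h,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = -max(cov$depth) * 0.05,
                   yend = -max(cov$depth) * 0.05),
      linewidth = 1.2, colour = "firebrick", inherit.aes = FALSE)
  }
  p
}

#' Plot gene models as exon boxes
#'
#' Exons are drawn as filled boxes, the CDS span as a darker overlay, and
#' transcripts are stacked per scaffold.
#'
#' @param genes Gene-model tibble.
#' @return A ggplot object.
#' @export
plot_gene_models <- function(genes) {
  g <- genes |>
    mutate(y = as.integer(factor(.data$transcript_id)))
  spans <- g |> group_by(.data$transcript_id) |>
    summarise(scaffold = .data$scaffold[1L], y = .data$y[1L],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  ggplot2::ggplot(g) +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y),
                          colour = "grey50") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$y - 0.3,
                                    ymax = .data$y + 0.3),
                       fill = "steelblue") +
    ggplot2::facet_wrap(~scaffold, scales = "free_x", ncol = 1L) +
    ggplot2::labs(x = "position (0-based)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn evaluate_predictions Bar chart of sensitivity and precision
#'   per feature level.
#' @param object A `prediction_eval` object.
#' @param ... Unused.
#' @export
autoplot.prediction_eval <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "precision"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
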