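#' GPS coverage plot
#'
#' Bar chart of per-region GPS coverage from a coverage summary, one bar
#' per facility type, with the national rollup leftmost.
#'
#' @param coverage Output of [coverage_summary()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  coverage |>
    dplyr::mutate(
      region = factor(.data$region,
                      levels = unique(c("National", sort(unique(.data$region)))))
    ) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$region, y = .data$pct_with_gps, fill = .data$fac_type
    )) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(
      x = NULL, y = "% facilities with GPS", fill = "Facility type",
      title = "GPS coverage by region and facility type"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_coverage
#' @param object A `facility_triangulation` object.
#' @param ... Unused.
#' @method autoplot facility_triangulation
#' @export
autoplot.facility_triangulation <- function(object, ...) {
  plot_coverage(coverage_summary(object$cfl))
}

#' Threshold-sweep plot
#'
#' Precision, recall and F1 as functions of the Jaro-Winkler distance
#' threshold.
#'
#' @param object A [threshold_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  object |>
    tidyr::pivot_longer(
      c("pairwise_precision", "pairwise_recall", "f1"),
      names_to = "metric", values_to = "value"
    ) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$threshold, y = .data$value, colour = .data$metric
    )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Jaro-Winkler distance threshold", y = NULL, colour = NULL,
      title = "Linkage quality across matching thresholds"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
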