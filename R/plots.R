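#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibration table as a quality-value grid
#'
#' Tiles of assigned QV by supporting-caller combination (rows) and
#' SV type / size class (columns), the standard way to inspect which
#' combinations the calibration trusts.
#'
#' @param object An `sv_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_calibration <- function(object, ...) {
  e <- dplyr::mutate(object$entries,
                     stratum = paste(.data$svtype, .data$size_bin, sep = "/"))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$stratum, y = .data$combination,
                                  fill = .data$qv)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$qv)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 40), name = "QV") +
    ggplot2::labs(x = "SV type / size class", y = "supporting callers",
                  title = "Calibrated quality values") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a benchmark report
#'
#' Precision, recall and F1 per size class and overall.
#'
#' @param object An `sv_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_benchmark <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size_bin, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "size class", y = NULL,
                  title = "Benchmark against the truth set") +
    ggplot2::theme_minimal()
}

#' Allele-frequency spectrum of a population SV table
#'
#' Histogram of allele frequencies on a log-scaled count axis; a healthy
#' cohort shows many rare SVs and few common or fixed ones.
#'
#' @param af_table Output of [population_af()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_af_spectrum <- function(af_table, bins = 20) {
  ggplot2::ggplot(af_table, ggplot2::aes(x = .data$af)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "allele frequency", y = "SV count (log scale)",
                  title = "Population allele-frequency spectrum") +
    ggplot2::theme_minimal()
}
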