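#' Plot simulated or measured spectra
#'
#' Overlays one spectrum per solution (first replicate by default),
#' coloured by concentration, with the evaluation intervals shaded.
#'
#' @param object A `raman_experiment`.
#' @param replicates Replicate indices to draw.
#' @param intervals Interval table to shade; `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raman_experiment <- function(object, replicates = 1L,
                                      intervals = ethanol_intervals(),
                                      ...) {
  df <- dplyr::filter(object$spectra, .data$replicate %in% !!replicates)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                        group = interaction(
                                          .data$sample_number,
                                          .data$replicate),
                                        colour = .data$concentration))
  if (!is.null(intervals)) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(xmin = .data$low, xmax = .data$high,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.5)
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "EtOH (Vol%)") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (counts)") +
    ggplot2::theme_minimal()
}

#' Accuracy-versus-concentration curve of a benchmark
#'
#' Mean leave-one-experiment-out accuracy per threshold on a log
#' concentration axis, with per-fold accuracies as points.
#'
#' @param object A `raman_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raman_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$threshold, .data$accuracy)) +
    ggplot2::geom_point(data = object$metrics, alpha = 0.3, size = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration threshold (Vol%)",
                  y = "Mean accuracy (%)") +
    ggplot2::theme_minimal()
}
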