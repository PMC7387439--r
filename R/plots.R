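#' Plot single-cell isotope enrichment distributions
#'
#' Violin-with-points view of per-cell atom percent for both isotopes,
#' with the activity thresholds drawn as dashed lines. Expects a
#' measurement tibble with `F_C` and `F_N` columns (fractions).
#'
#' @param meas ROI measurement tibble ([measure_rois()] or
#'   [classify_active()] output).
#' @param setup Optional [incubation_setup()] supplying the thresholds.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(meas, setup = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(meas), "roi_id", "F_C", "F_N"),
    c("F_C", "F_N"),
    names_to = "isotope", values_to = "F"
  )
  long$isotope <- dplyr::recode(long$isotope, F_C = "13C", F_N = "15N")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$isotope,
                                          y = 100 * .data$F)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "atom %") +
    ggplot2::theme_minimal()
  if (!is.null(setup)) {
    thr <- tibble::tibble(isotope = c("13C", "15N"),
                          threshold = 100 * c(setup$threshold_C,
                                              setup$threshold_N))
    p <- p + ggplot2::geom_hline(
      data = thr,
      ggplot2::aes(yintercept = .data$threshold),
      linetype = "dashed", colour = "firebrick"
    ) + ggplot2::facet_wrap(~isotope, scales = "free_y")
  }
  p
}

#' Plot a cell-count time series
#'
#' Cell abundance over incubation time on a log axis.
#'
#' @param series Tibble with `day` and `cells_per_cm3` (and optionally a
#'   grouping column named `sample_id`).
#' @return A ggplot object.
#' @export
plot_growth <- function(series) {
  aes <- if ("sample_id" %in% names(series)) {
    ggplot2::aes(.data$day, .data$cells_per_cm3,
                 colour = .data$sample_id, group = .data$sample_id)
  } else {
    ggplot2::aes(.data$day, .data$cells_per_cm3)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "incubation time (days)",
                  y = expression(cells ~ cm^-3)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_imf_calibration Plot the standards and fitted line.
#' @param object An `imf_calibration`.
#' @export
autoplot.imf_calibration <- function(object, ...) {
  if (is.null(object$data)) abort("identity calibration has no standards to plot")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$instrument, .data$reference)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "instrument ratio", y = "reference (bulk) ratio",
                  title = sprintf("IMF calibration (%s)", object$isotope)) +
    ggplot2::theme_minimal()
}
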