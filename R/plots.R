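# ggplot2 displays for histogram calibration and group summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the DAPI+ region size histogram
#'
#' The bound-selection display: pooled region areas as bars, with the
#' fitted first-peak bounds and mean single-nucleus area marked when a
#' calibration model is supplied. The first peak at small areas collects
#' the single nuclei; the broader shoulder to its right, doublets and
#' triplets; the tail, larger clumps.
#'
#' @param object an `area_histogram` from [build_area_histogram()].
#' @param calibration optional [fit_calibration()] model to annotate.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot area_histogram
#' @export
autoplot.area_histogram <- function(object, calibration = NULL, ...) {
  df <- tibble::as_tibble(object[c("bin_lower", "bin_upper", "count")])
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_col(ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                                   y = .data$count),
                      width = attr(object, "bin_width"),
                      fill = "#4477AA", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "DAPI+ region area (px)", y = "regions",
                  title = "Pooled DAPI+ region size distribution") +
    ggplot2::theme_minimal()
  if (!is.null(calibration)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(calibration$first_peak_lower,
                                         calibration$first_peak_upper),
                          linetype = "dashed", colour = "#CC3311") +
      ggplot2::geom_vline(xintercept = calibration$mean_single_area,
                          colour = "#CC3311")
  }
  p
}

#' Plot group means with 95% confidence intervals
#'
#' Point-and-interval display of one or more [summarize_group()] rows,
#' mirroring the mean/CI bar presentation of CFC group comparisons.
#'
#' @param summaries tibble of group summary rows; a `group` column, if
#'   present, is mapped to the x axis.
#' @return a ggplot object.
#' @export
plot_group_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (!"group" %in% names(summaries)) summaries$group <- "group"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             colour = "#4477AA") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean (95% CI)") +
    ggplot2::theme_minimal()
}
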