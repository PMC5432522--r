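#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a growth series
#'
#' Counts against culture time on a log2 y-axis; exponential growth is a
#' straight line whose slope is the inverse doubling time.
#'
#' @param object a `growth_series` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot growth_series
#' @export
autoplot.growth_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$count_per_well)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "culture time [h]", y = "cells per well (log2 scale)")
}

#' Plot a log-linear growth fit
#'
#' @param object a `growth_fit` from [doubling_time_loglinear()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  e <- object$estimate
  lab <- if (e$growth) sprintf("Td = %.1f h (R2 = %.3f)", e$doubling_time_h, e$r_squared) else "no growth"
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$time_h, y = log2(.data$count))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(x = "culture time [h]", y = "log2(count)", subtitle = lab)
}

#' Plot an automated-vs-manual count comparison
#'
#' @param object a `count_comparison` from [compare_counts()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot count_comparison
#' @export
autoplot.count_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$automated, y = .data$manual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = if (object$intercept) stats::coef(object$model)[1] else 0,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "automated count", y = "manual count",
                  subtitle = sprintf("slope = %.2f, R2 = %.2f", object$slope, object$r_squared))
}

#' Plot an aggregate-formation track
#'
#' @param object an `aggregate_track` from [track_aggregate()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot aggregate_track
#' @export
autoplot.aggregate_track <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("area_um2", "circularity", "n_fragments"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [h]", y = NULL)
}

#' Passage-trend panel for QC results
#'
#' Doubling time, mean projected area and mean circularity against passage
#' number, points coloured by QC status.
#'
#' @param qc a `qc_result` from [evaluate_qc()].
#' @return a ggplot object.
#' @export
plot_passage_trends <- function(qc) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(qc), "passage_number", "status",
                  "doubling_time_h", "area_mean_um2", "circularity_mean"),
    cols = c("doubling_time_h", "area_mean_um2", "circularity_mean"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$passage_number, y = .data$value,
                                     colour = .data$status)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "passage number", y = NULL, colour = "QC status")
}

#' Display a calibrated image (and optional overlays) with ggplot2
#'
#' @param object a [calibrated_image()].
#' @param cells optional tibble with `cx_um`, `cy_um` to overlay detected
#'   centroids.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cellmon_image
#' @export
autoplot.cellmon_image <- function(object, cells = NULL, ...) {
  px <- object$pixels
  df <- expand.grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$value <- as.vector(px)
  df$x_um <- (df$x - 0.5) * object$pixel_size_x_um
  df$y_um <- (df$y - 0.5) * object$pixel_size_y_um
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [um]", y = "y [um]", fill = "luminance")
  if (!is.null(cells)) {
    p <- p + ggplot2::geom_point(data = cells,
                                 ggplot2::aes(x = .data$cx_um, y = .data$cy_um),
                                 colour = "dodgerblue", size = 1)
  }
  p
}
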