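#' Extrapolate a per-well count from region counts
#'
#' The per-well population is estimated as the mean of the region counts
#' scaled by the well-to-field area ratio, assuming uniform cell density
#' across the well (the implicit assumption behind averaging a handful of
#' regions).
#'
#' @param region_counts numeric vector of per-region cell counts (>= 1
#'   value).
#' @param layout a [plate_layout()] supplying well and field areas.
#' @return estimated cells per well (numeric scalar).
#' @export
well_count_from_regions <- function(region_counts, layout = plate_layout()) {
  if (length(region_counts) < 1L) {
    stop("at least one region count is required", call. = FALSE)
  }
  stopifnot(all(region_counts >= 0), inherits(layout, "plate_layout"))
  mean(region_counts) * layout$well_area_mm2 / field_area_mm2(layout)
}

#' Assemble a per-well growth series from region counts
#'
#' @param df a data frame with columns `time_h` and `count` (one row per
#'   region observation).
#' @param layout a [plate_layout()].
#' @return a tibble of class `growth_series` with columns `time_h`,
#'   `count_per_well`, `n_regions`, `region_counts` (list column), sorted
#'   by time.
#' @export
growth_series <- function(df, layout = plate_layout()) {
  stopifnot(is.data.frame(df), all(c("time_h", "count") %in% names(df)))
  out <- df |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      count_per_well = well_count_from_regions(.data$count, layout),
      n_regions = dplyr::n(),
      region_counts = list(.data$count),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_h)
  class(out) <- c("growth_series", class(out))
  out
}

new_growth_estimate <- function(doubling_time_h, method, t1_h, t2_h,
                                r_squared = NA_real_, growth = TRUE) {
  tibble::tibble(doubling_time_h = doubling_time_h, method = method,
                 t1_h = t1_h, t2_h = t2_h, r_squared = r_squared,
                 growth = growth)
}

#' Doubling time from two endpoint counts
#'
#' `Td = (t2 - t1) * ln(2) / ln(n2 / n1)` under exponential growth. When
#' `n2 <= n1` no growth is detected: the estimate carries
#' `growth = FALSE` and an `NA` doubling time instead of an error.
#'
#' @param n1,t1_h count and time at the first endpoint (`n1 > 0`).
#' @param n2,t2_h count and time at the second endpoint (`t2_h > t1_h`).
#' @return a one-row tibble: `doubling_time_h`, `method`, `t1_h`, `t2_h`,
#'   `r_squared` (`NA` for this method), `growth`.
#' @export
doubling_time_endpoint <- function(n1, t1_h, n2, t2_h) {
  if (!is.finite(n1) || n1 <= 0) stop("n1 must be positive", call. = FALSE)
  if (!is.finite(t2_h) || !is.finite(t1_h) || t2_h <= t1_h) {
    stop("endpoints must satisfy t2_h > t1_h", call. = FALSE)
  }
  if (!is.finite(n2) || n2 < 0) stop("n2 must be non-negative", call. = FALSE)
  if (n2 <= n1) {
    return(new_growth_estimate(NA_real_, "endpoint", t1_h, t2_h, growth = FALSE))
  }
  td <- (t2_h - t1_h) * log(2) / log(n2 / n1)
  new_growth_estimate(td, "endpoint", t1_h, t2_h)
}

#' Doubling time from a log-linear fit
#'
#' Least-squares fit of `log2(count)` against time over the whole series;
#' the doubling time is the reciprocal of the slope. More robust than the
#' two-endpoint formula when counts are noisy. A non-positive slope yields
#' a non-growth marker (`growth = FALSE`).
#'
#' @param series a data frame with columns `time_h` and a count column
#'   (`count_per_well` or `count`), e.g. a [growth_series()]; at least 3
#'   points, all counts strictly positive.
#' @return an object of class `growth_fit`: the one-row estimate tibble is
#'   available via [glance()][generics::glance], per-term coefficients via
#'   [tidy()][generics::tidy], and `$estimate`, `$model`, `$series` hold
#'   the parts.
#' @export
doubling_time_loglinear <- function(series) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series))
  cname <- intersect(c("count_per_well", "count"), names(series))[1]
  if (is.na(cname)) stop("series must have a 'count' or 'count_per_well' column",
                         call. = FALSE)
  n <- series[[cname]]; t <- series$time_h
  if (length(n) < 3L) stop("at least 3 points are required", call. = FALSE)
  bad <- which(!is.finite(n) | n <= 0)
  if (length(bad)) {
    stop("non-positive count at time_h = ",
         paste(t[bad], collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(log2(n) ~ t)
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  est <- if (slope <= 0) {
    new_growth_estimate(NA_real_, "loglinear", min(t), max(t),
                        r_squared = r2, growth = FALSE)
  } else {
    new_growth_estimate(1 / slope, "loglinear", min(t), max(t), r_squared = r2)
  }
  structure(list(estimate = est, model = fit,
                 series = tibble::tibble(time_h = t, count = n)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  e <- x$estimate
  if (e$growth) {
    cat(sprintf("<growth_fit> Td = %.3g h (log-linear over %g-%g h, R2 = %.3f)\n",
                e$doubling_time_h, e$t1_h, e$t2_h, e$r_squared))
  } else {
    cat("<growth_fit> no growth detected (non-positive slope)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname doubling_time_loglinear
#' @param x a `growth_fit`.
#' @param ... unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = c("(Intercept)", "time_h"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname doubling_time_loglinear
#' @export
glance.growth_fit <- function(x, ...) {
  dplyr::mutate(x$estimate, n = nrow(x$series))
}

#' Compare automated against manual counts
#'
#' Through-origin least-squares regression of manual counts on automated
#' counts (`slope = sum(xy) / sum(x^2)`); the coefficient of determination
#' is computed against the through-origin fit (uncentred total sum of
#' squares). A slope below 1 means the automated method counts more cells
#' than the manual reference. Set `intercept = TRUE` for an
#' ordinary-intercept regression instead.
#'
#' @param pairs a data frame with columns `automated` and `manual`, one
#'   row per paired measurement (>= 2 rows, positive values).
#' @param intercept fit an ordinary intercept model instead of
#'   through-origin.
#' @return an object of class `count_comparison` with `$slope`,
#'   `$r_squared`, `$n_pairs`, `$model`, `$data`; [glance()] returns them
#'   as a one-row tibble.
#' @export
compare_counts <- function(pairs, intercept = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("automated", "manual") %in% names(pairs)))
  if (nrow(pairs) < 2L) stop("at least 2 count pairs are required", call. = FALSE)
  if (any(pairs$automated <= 0) || any(pairs$manual <= 0)) {
    stop("count pairs must be positive", call. = FALSE)
  }
  fit <- if (intercept) {
    stats::lm(manual ~ automated, data = pairs)
  } else {
    stats::lm(manual ~ 0 + automated, data = pairs)
  }
  slope <- unname(stats::coef(fit)[["automated"]])
  structure(
    list(slope = slope, r_squared = suppressWarnings(summary(fit)$r.squared),
         n_pairs = nrow(pairs), intercept = intercept,
         model = fit, data = tibble::as_tibble(pairs)),
    class = "count_comparison"
  )
}

#' @export
print.count_comparison <- function(x, ...) {
  cat(sprintf("<count_comparison> slope = %.3f, R2 = %.3f (n = %d%s)\n",
              x$slope, x$r_squared, x$n_pairs,
              if (x$intercept) ", with intercept" else ", through origin"))
  invisible(x)
}

#' @rdname compare_counts
#' @param x a `count_comparison`.
#' @param ... unused.
#' @export
glance.count_comparison <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared, n_pairs = x$n_pairs)
}

#' @rdname compare_counts
#' @export
tidy.count_comparison <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Count cells across a simulated or loaded frame series
#'
#' Convenience pipeline: run [detect_cells()] on each frame and return the
#' per-frame counts as a growth series (per-field counts, no well
#' extrapolation).
#'
#' @param frames a list of [calibrated_image()] frames, or a
#'   `synth_timelapse` result.
#' @param params a [segmentation_params()].
#' @return a tibble with `time_h` and `count` (one row per frame).
#' @export
count_frames <- function(frames, params = segmentation_params()) {
  if (inherits(frames, "synth_timelapse")) {
    frames <- lapply(frames$frames, `[[`, "image")
  }
  purrr::map_dfr(frames, function(img) {
    det <- detect_cells(img, params)
    tibble::tibble(time_h = img$time_h, count = det$n_cells)
  })
}
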