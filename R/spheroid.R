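#' Detect a microwell grid in a chip image
#'
#' Matched-filter detection: the image is inverted around its median (wells
#' image darker than the chip surface), correlated with a disc template of
#' the well diameter, and local maxima separated by at least ~70% of the
#' expected pitch are kept. Nearest-neighbour spacing is checked against
#' the expected pitch.
#'
#' @param img a [calibrated_image()] of the chip.
#' @param pitch_um expected centre-to-centre spacing (default 600).
#' @param well_diameter_um microwell diameter (default 500).
#' @param n_wells maximum number of wells to report (default 100).
#' @param min_contrast minimum mean luminance contrast (units) between well
#'   interior and surroundings for a peak to count as a detection.
#' @return an object of class `microwell_grid`: tibble `centers`
#'   (cx_px, cy_px, cx_um, cy_um, response) plus geometry fields.
#' @export
detect_grid <- function(img, pitch_um = 600, well_diameter_um = 500,
                        n_wells = 100L, min_contrast = 5) {
  stopifnot(inherits(img, "cellmon_image"))
  ps <- img$pixel_size_x_um
  pitch_px <- pitch_um / ps
  r_px <- well_diameter_um / 2 / ps
  px <- img$pixels
  if (min(dim(px)) < 2 * r_px) {
    stop("image does not span a full microwell at this calibration", call. = FALSE)
  }
  signal <- stats::median(px) - px          # wells are darker than the chip
  # disc matched filter, normalised to mean contrast over the disc
  dside <- 2L * floor(r_px * 0.8) + 1L
  disc <- EBImage::makeBrush(dside, shape = "disc")
  disc <- disc / sum(disc)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(signal), disc,
                                              boundary = "replicate"))
  # local maxima within half a pitch
  wr <- max(3L, floor(pitch_px * 0.35))
  mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(resp),
                                           EBImage::makeBrush(2L * wr + 1L, "box")))
  peaks <- which(resp >= mx - 1e-9 & resp > min_contrast)
  if (!length(peaks)) {
    stop("no microwell pattern detected: peak matched-filter response ",
         signif(max(resp), 3), " is below the contrast floor ", min_contrast,
         call. = FALSE)
  }
  co <- arrayInd(peaks, dim(resp))
  centers <- tibble::tibble(
    cx_px = co[, 2] - 0.5, cy_px = co[, 1] - 0.5,
    response = resp[peaks]
  )
  # suppress duplicate plateau peaks closer than 0.7 pitch, keep strongest
  ord <- order(-centers$response)
  keep <- logical(nrow(centers))
  for (i in ord) {
    if (any(keep & (centers$cx_px - centers$cx_px[i])^2 +
            (centers$cy_px - centers$cy_px[i])^2 < (0.7 * pitch_px)^2)) next
    keep[i] <- TRUE
  }
  centers <- centers[keep, ]
  if (nrow(centers) > n_wells) {
    centers <- centers[order(-centers$response)[seq_len(n_wells)], ]
  }
  centers$cx_um <- centers$cx_px * ps
  centers$cy_um <- centers$cy_px * img$pixel_size_y_um
  centers <- dplyr::arrange(centers, .data$cy_px, .data$cx_px)
  if (nrow(centers) > 1) {
    nn <- vapply(seq_len(nrow(centers)), function(i) {
      d <- sqrt((centers$cx_um - centers$cx_um[i])^2 +
                  (centers$cy_um - centers$cy_um[i])^2)
      min(d[-i])
    }, numeric(1))
    off <- abs(nn - pitch_um) / pitch_um
    if (stats::median(off) > 0.10) {
      stop("detected peaks are not spaced at the expected pitch (median ",
           "nearest-neighbour distance ", signif(stats::median(nn), 4),
           " um vs pitch ", pitch_um, " um)", call. = FALSE)
    }
  }
  structure(list(centers = centers, pitch_um = pitch_um,
                 well_diameter_um = well_diameter_um,
                 n_detected = nrow(centers)),
            class = "microwell_grid")
}

#' @export
print.microwell_grid <- function(x, ...) {
  cat(sprintf("<microwell_grid> %d wells detected (pitch %g um, diameter %g um)\n",
              x$n_detected, x$pitch_um, x$well_diameter_um))
  invisible(x)
}

#' Track aggregate formation in one microwell
#'
#' Segments each frame of a per-microwell image series (texture-energy
#' binarization, as for cell fields but without watershed splitting, since
#' an aggregate is a single object) and records the total projected area,
#' the circularity of the largest fragment, and the fragment count.
#'
#' @param frames list of [calibrated_image()] frames of one microwell ROI
#'   (>= 2), or a `synth_spheroid_series`.
#' @param params a [segmentation_params()]; defaults are scaled to the
#'   aggregate regime: Otsu threshold (aggregate frames are far from the
#'   mostly-background regime the robust noise floor assumes), coarser
#'   texture and refinement scales, and a single-cell minimum object size.
#'   `split_touching` is forced off, since an aggregate is a single object.
#' @return a tibble of class `aggregate_track`: `time_h`, `area_um2`,
#'   `circularity`, `n_fragments`.
#' @export
track_aggregate <- function(frames,
                            params = segmentation_params(
                              texture_scale_um = 4,
                              refine_scale_um = 2,
                              threshold_method = "otsu",
                              min_cell_area_um2 = 200,
                              split_touching = FALSE)) {
  if (inherits(frames, "synth_spheroid_series")) frames <- frames$frames
  if (length(frames) < 2L) {
    stop("at least 2 frames are required to track an aggregate", call. = FALSE)
  }
  params$split_touching <- FALSE
  rows <- purrr::map_dfr(frames, function(img) {
    det <- detect_cells(img, params)
    if (det$n_cells == 0L) {
      return(tibble::tibble(time_h = img$time_h, area_um2 = 0,
                            circularity = NA_real_, n_fragments = 0L))
    }
    rec <- measure_cells(det)
    big <- which.max(rec$area_um2)
    tibble::tibble(time_h = img$time_h,
                   area_um2 = sum(rec$area_um2),
                   circularity = rec$circularity[big],
                   n_fragments = det$n_cells)
  })
  class(rows) <- c("aggregate_track", class(rows))
  rows
}

#' Classify aggregate-formation dynamics
#'
#' Operationalizes the qualitative regimes of microwell spheroid
#' formation:
#' * `"compacting"` - the track ends as a single fragment of circularity
#'   at least `circularity_min` and the projected area does not rise over
#'   the last half of the track (a smooth spheroid has condensed);
#' * `"dissociating"` - after an initial aggregation phase the fragment
#'   count rises to at least `frag_rise_factor` times its minimum (the
#'   aggregate broke back up into single cells);
#' * `"none"` otherwise (cells stayed scattered).
#'
#' @param track an [track_aggregate()] result (>= `min_samples` rows).
#' @param circularity_min circularity floor for a compacted spheroid.
#' @param frag_rise_factor fragment-count rise factor for dissociation.
#' @param area_rise_tol tolerated relative area rise over the last half of
#'   the track (fraction of the mean area) before "compacting" is ruled
#'   out.
#' @param min_samples minimum number of samples in the track.
#' @return one of `"compacting"`, `"dissociating"`, `"none"`.
#' @export
classify_dynamics <- function(track,
                              circularity_min = 0.8,
                              frag_rise_factor = 3,
                              area_rise_tol = 0.10,
                              min_samples = 3L) {
  stopifnot(is.data.frame(track),
            all(c("time_h", "area_um2", "circularity", "n_fragments") %in% names(track)))
  n <- nrow(track)
  if (n < min_samples) {
    stop("track has ", n, " samples; at least ", min_samples, " are required",
         call. = FALSE)
  }
  last <- track[n, ]
  # compacting: single smooth fragment, no area growth over the last half
  second_half <- track[track$time_h >= stats::median(track$time_h), ]
  area_slope <- if (nrow(second_half) >= 2) {
    unname(stats::coef(stats::lm(area_um2 ~ time_h, data = second_half))[2])
  } else 0
  span <- max(second_half$time_h) - min(second_half$time_h)
  rel_rise <- if (span > 0 && mean(second_half$area_um2) > 0) {
    area_slope * span / mean(second_half$area_um2)
  } else 0
  if (last$n_fragments == 1L && isTRUE(last$circularity >= circularity_min) &&
      rel_rise <= area_rise_tol) {
    return("compacting")
  }
  # dissociating: fragment count rises well above its minimum after
  # an aggregation phase
  i_min <- which.min(track$n_fragments)
  f_min <- max(track$n_fragments[i_min], 1L)
  if (i_min < n) {
    f_after <- max(track$n_fragments[i_min:n])
    if (f_after >= frag_rise_factor * f_min) return("dissociating")
  }
  "none"
}

#' Equivalent circular diameter of the final aggregate
#'
#' @param track an [track_aggregate()] result.
#' @return diameter in um of a circle with the final frame's projected
#'   area.
#' @export
final_equivalent_diameter <- function(track) {
  a <- track$area_um2[nrow(track)]
  2 * sqrt(a / pi)
}
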