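#' Calibrated grayscale image
#'
#' A single 8-bit grayscale frame together with its physical pixel
#' calibration and acquisition metadata (plate, well, region, culture time).
#' Pixels are stored as a numeric matrix in `[0, 255]` with rows running
#' along image y and columns along image x.
#'
#' The default calibration of 0.463 um/px corresponds to a 1.2 mm field
#' width imaged on a 2592-px sensor line; square pixels are assumed unless
#' both sizes are given.
#'
#' @param pixels numeric matrix of luminance values in `[0, 255]`.
#' @param pixel_size_x_um,pixel_size_y_um physical size of one pixel, in
#'   micrometres. Strictly positive.
#' @param time_h culture time in hours (numeric, may be `NA`).
#' @param plate_id plate identifier (character, may be `NA`).
#' @param well_row,well_col 0-based well coordinates (may be `NA`).
#' @param region_index 0-based region index within the well (may be `NA`).
#' @return an object of class `cellmon_image`.
#' @export
calibrated_image <- function(pixels,
                             pixel_size_x_um = 0.463,
                             pixel_size_y_um = pixel_size_x_um,
                             time_h = NA_real_,
                             plate_id = NA_character_,
                             well_row = NA_integer_,
                             well_col = NA_integer_,
                             region_index = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix; got ",
         paste(class(pixels), collapse = "/"),
         if (is.array(pixels)) paste0(" with dim [", paste(dim(pixels), collapse = ", "), "]") else "",
         call. = FALSE)
  }
  if (any(dim(pixels) < 1L)) stop("image dimensions must both be >= 1", call. = FALSE)
  if (!is.finite(pixel_size_x_um) || pixel_size_x_um <= 0 ||
      !is.finite(pixel_size_y_um) || pixel_size_y_um <= 0) {
    stop("pixel sizes must be strictly positive", call. = FALSE)
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("luminance values must lie within [0, 255]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      pixel_size_x_um = as.numeric(pixel_size_x_um),
      pixel_size_y_um = as.numeric(pixel_size_y_um),
      time_h = as.numeric(time_h),
      plate_id = as.character(plate_id),
      well_row = as.integer(well_row),
      well_col = as.integer(well_col),
      region_index = as.integer(region_index)
    ),
    class = "cellmon_image"
  )
}

#' @export
print.cellmon_image <- function(x, ...) {
  cat(sprintf(
    "<cellmon_image> %d x %d px (%.3g x %.3g um/px), t = %s h\n",
    ncol(x$pixels), nrow(x$pixels),
    x$pixel_size_x_um, x$pixel_size_y_um,
    format(x$time_h)
  ))
  invisible(x)
}

#' @export
dim.cellmon_image <- function(x) dim(x$pixels)

#' Physical pixel area in square micrometres
#' @param img a `cellmon_image`.
#' @return scalar, `pixel_size_x_um * pixel_size_y_um`.
#' @export
pixel_area_um2 <- function(img) img$pixel_size_x_um * img$pixel_size_y_um

#' Load a grayscale TIFF or PNG as a calibrated image
#'
#' Reads a single-page grayscale TIFF or PNG. 16-bit input is rescaled
#' linearly so that the representable maximum maps to 255. Multi-channel
#' (RGB/RGBA) input is rejected: relief-contrast acquisition is
#' single-channel by construction and silent channel mixing would corrupt
#' luminance-based measurements.
#'
#' @param path file path; format is decided by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @param pixel_size_x_um,pixel_size_y_um,time_h,plate_id,well_row,well_col,region_index
#'   calibration and metadata, as in [calibrated_image()].
#' @return a `cellmon_image`.
#' @export
load_image <- function(path,
                       pixel_size_x_um = 0.463,
                       pixel_size_y_um = pixel_size_x_um,
                       time_h = NA_real_,
                       plate_id = NA_character_,
                       well_row = NA_integer_,
                       well_col = NA_integer_,
                       region_index = NA_integer_) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, info = FALSE),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (expected TIFF or PNG)", call. = FALSE)
  )
  if (is.list(raw)) stop("multi-page images are not supported by load_image()", call. = FALSE)
  if (length(dim(raw)) != 2L) {
    stop("expected a 2-D grayscale image; got array with dim [",
         paste(dim(raw), collapse = ", "), "] (multi-channel input?)", call. = FALSE)
  }
  # readTIFF/readPNG return values in [0, 1]; rescale to 8-bit range so that
  # the input maximum representable value maps to 255.
  px <- raw * 255
  calibrated_image(px,
                   pixel_size_x_um = pixel_size_x_um,
                   pixel_size_y_um = pixel_size_y_um,
                   time_h = time_h, plate_id = plate_id,
                   well_row = well_row, well_col = well_col,
                   region_index = region_index)
}

#' Save a calibrated image as 8-bit TIFF or PNG
#'
#' Values are rounded to the nearest integer in `[0, 255]` and written
#' losslessly, so an 8-bit save/load cycle round-trips pixel data exactly.
#'
#' @param img a `cellmon_image`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "cellmon_image"))
  m <- pmin(pmax(round(img$pixels), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none"),
    png = png::writePNG(m, path),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Multiwell plate layout
#'
#' Describes the well grid of a culture plate and the imaged field, used to
#' extrapolate per-field counts to per-well counts. Defaults describe a
#' 6-well plate (2 x 3 wells of 9.6 cm2 growth area) imaged at 5 regions
#' per well with a 1.2 mm x 0.8 mm field.
#'
#' @param n_rows,n_cols well-grid dimensions.
#' @param well_area_mm2 growth area per well, mm2.
#' @param regions_per_well number of imaged regions per well (>= 1).
#' @param field_width_mm,field_height_mm physical size of one imaged field.
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(n_rows = 2L, n_cols = 3L,
                         well_area_mm2 = 960,
                         regions_per_well = 5L,
                         field_width_mm = 1.2,
                         field_height_mm = 0.8) {
  stopifnot(n_rows >= 1, n_cols >= 1, well_area_mm2 > 0, regions_per_well >= 1,
            field_width_mm > 0, field_height_mm > 0)
  if (field_width_mm * field_height_mm > well_area_mm2) {
    stop("imaged field area exceeds the well growth area", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         well_area_mm2 = well_area_mm2,
         regions_per_well = as.integer(regions_per_well),
         field_width_mm = field_width_mm, field_height_mm = field_height_mm),
    class = "plate_layout"
  )
}

#' Total number of monitored regions on one plate
#'
#' @param layout a [plate_layout()].
#' @return integer, `n_rows * n_cols * regions_per_well` (30 for the default
#'   6-well plate at 5 regions/well).
#' @export
regions_per_plate <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  layout$n_rows * layout$n_cols * layout$regions_per_well
}

#' Imaged field area in mm2
#' @param layout a [plate_layout()].
#' @return scalar field area.
#' @export
field_area_mm2 <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  layout$field_width_mm * layout$field_height_mm
}

#' Acquisition schedule
#'
#' Periodic imaging over a culture-time window. Frames tick at
#' `interval_min` over the half-open window `[start_h, end_h)`: monitoring
#' hourly from 24 h to 72 h yields 48 frames per region per passage.
#'
#' @param start_h,end_h culture-time window bounds in hours (`end_h > start_h`).
#' @param interval_min acquisition period in minutes (> 0).
#' @param regions total monitored regions per passage.
#' @param n_passages number of passage runs monitored.
#' @return an object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(start_h = 24, end_h = 72, interval_min = 60,
                                 regions = 30L, n_passages = 1L) {
  if (!is.finite(start_h) || !is.finite(end_h) || end_h <= start_h) {
    stop("schedule window must satisfy end_h > start_h", call. = FALSE)
  }
  if (!is.finite(interval_min) || interval_min <= 0) {
    stop("interval_min must be positive", call. = FALSE)
  }
  stopifnot(regions >= 1, n_passages >= 1)
  structure(
    list(start_h = start_h, end_h = end_h, interval_min = interval_min,
         regions = as.integer(regions), n_passages = as.integer(n_passages)),
    class = "acquisition_schedule"
  )
}

#' Number of frames per region per passage
#' @param schedule an [acquisition_schedule()].
#' @return integer frame count over the half-open window.
#' @export
frames_per_region <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  as.integer(floor((schedule$end_h - schedule$start_h) * 60 / schedule$interval_min))
}

#' Expand an acquisition schedule into per-image events
#'
#' One row per (passage, region, frame). The total number of rows is
#' `frames x regions x n_passages`; for the default hourly 24-72 h window
#' at 10 regions over 12 passages this is 5760 images.
#'
#' @param schedule an [acquisition_schedule()].
#' @return a tibble with columns `passage`, `region`, `frame`, `time_h`,
#'   ordered by passage, then region, then frame.
#' @export
plan_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  nf <- frames_per_region(schedule)
  ev <- tidyr::expand_grid(
    passage = seq_len(schedule$n_passages),
    region = seq_len(schedule$regions) - 1L,
    frame = seq_len(nf) - 1L
  )
  ev$time_h <- schedule$start_h + ev$frame * schedule$interval_min / 60
  tibble::as_tibble(ev)
}

#' Total image count implied by a schedule
#' @param schedule an [acquisition_schedule()].
#' @return integer, frames per region x regions x passages.
#' @export
total_image_count <- function(schedule) {
  frames_per_region(schedule) * schedule$regions * schedule$n_passages
}

#' Read a run configuration from YAML
#'
#' The file may contain `layout:` and `schedule:` blocks whose keys mirror
#' the arguments of [plate_layout()] and [acquisition_schedule()]; missing
#' keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return a list with elements `layout` and `schedule`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layout <- do.call(plate_layout, cfg$layout %||% list())
  schedule <- do.call(acquisition_schedule, cfg$schedule %||% list())
  list(layout = layout, schedule = schedule)
}

#' Read an image manifest
#'
#' A manifest CSV lists acquired frames with columns `path`, `plate`,
#' `well_row`, `well_col`, `region`, `time_h`.
#'
#' @param path path to the CSV file.
#' @param base_dir directory against which relative `path` entries are
#'   resolved; defaults to the manifest's own directory.
#' @return a tibble with the manifest columns, `path` made absolute.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "plate", "well_row", "well_col", "region", "time_h")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(base_dir, m$path[rel])
  tibble::as_tibble(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
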