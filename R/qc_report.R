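#' Assemble a passage profile table
#'
#' One row per monitored passage with the metrics the QC rules evaluate.
#'
#' @param passage_number integer passage numbers (>= 1).
#' @param doubling_time_h estimated doubling times, hours.
#' @param area_mean_um2 mean projected cell areas, um2.
#' @param circularity_mean mean circularities.
#' @param confluency_final final-frame confluency fractions (optional).
#' @return a tibble of class `passage_profile`.
#' @export
passage_profile <- function(passage_number, doubling_time_h, area_mean_um2,
                            circularity_mean, confluency_final = NA_real_) {
  stopifnot(all(passage_number >= 1))
  out <- tibble::tibble(
    passage_number = as.integer(passage_number),
    doubling_time_h = doubling_time_h,
    area_mean_um2 = area_mean_um2,
    circularity_mean = circularity_mean,
    confluency_final = confluency_final
  )
  class(out) <- c("passage_profile", class(out))
  out
}

#' Culture quality-control rules
#'
#' Numeric bands operationalizing the two failure patterns seen across
#' passage culture of endothelial cells: a senescence-like pattern
#' (slowing proliferation with enlarged cells) and a transformation-like
#' pattern (accelerating proliferation with small, spindle-shaped cells).
#' Defaults bracket the healthy early-passage anchors (~20 h doubling
#' time, ~80 um2 projected area) with a +/-30% tolerance.
#'
#' @param td_band_h acceptable doubling-time band, hours `c(low, high)`.
#' @param area_band_um2 acceptable mean-area band, um2 `c(low, high)`.
#' @param circularity_min circularity floor below which cells count as
#'   spindle-shaped.
#' @return an object of class `qc_rules`.
#' @export
qc_rules <- function(td_band_h = c(14, 26),
                     area_band_um2 = c(56, 104),
                     circularity_min = 0.5) {
  stopifnot(length(td_band_h) == 2, td_band_h[1] < td_band_h[2],
            length(area_band_um2) == 2, area_band_um2[1] < area_band_um2[2],
            circularity_min > 0, circularity_min < 1)
  structure(list(td_band_h = td_band_h, area_band_um2 = area_band_um2,
                 circularity_min = circularity_min),
            class = "qc_rules")
}

QC_ADVISORY <- paste(
  "Cultures flagged here match proliferation/morphology patterns that have",
  "been associated with loss of angiogenic competence in subsequent",
  "hydrogel assays; treat the flag as an advisory, not a functional assay."
)

#' Evaluate quality-control flags for passage profiles
#'
#' Flags are additive and deterministic; the bands are open acceptable
#' intervals, so a metric sitting exactly on a band edge counts as
#' out-of-band:
#' * `SENESCENCE_SUSPECT` - doubling time at/above the band high AND mean
#'   area at/above the area band high (cell-cycle slowdown with cell
#'   enlargement);
#' * `TRANSFORMATION_SUSPECT` - doubling time at/below the band low AND
#'   mean area at/below the area band low AND mean circularity below
#'   `circularity_min` (fast-growing small spindle-shaped cells).
#'
#' A profile with no flag is `OK`.
#'
#' @param profiles a [passage_profile()] tibble (or any data frame with
#'   its columns).
#' @param rules a [qc_rules()].
#' @return the input tibble with added columns `flags` (list of character
#'   vectors), `status` (`"OK"` or the flags collapsed with `+`) and
#'   `advisory` (character, `NA` when unflagged).
#' @export
evaluate_qc <- function(profiles, rules = qc_rules()) {
  stopifnot(is.data.frame(profiles), inherits(rules, "qc_rules"))
  need <- c("passage_number", "doubling_time_h", "area_mean_um2", "circularity_mean")
  for (f in need) {
    if (!f %in% names(profiles)) {
      stop("profile is missing required metric '", f, "'", call. = FALSE)
    }
    if (anyNA(profiles[[f]])) {
      stop("profile metric '", f, "' contains missing values", call. = FALSE)
    }
  }
  flags <- purrr::pmap(
    list(profiles$doubling_time_h, profiles$area_mean_um2, profiles$circularity_mean),
    function(td, area, circ) {
      out <- character(0)
      if (td >= rules$td_band_h[2] && area >= rules$area_band_um2[2]) {
        out <- c(out, "SENESCENCE_SUSPECT")
      }
      if (td <= rules$td_band_h[1] && area <= rules$area_band_um2[1] &&
          circ < rules$circularity_min) {
        out <- c(out, "TRANSFORMATION_SUSPECT")
      }
      out
    }
  )
  out <- tibble::as_tibble(profiles)
  out$flags <- flags
  out$status <- vapply(flags, function(f) {
    if (length(f)) paste(f, collapse = "+") else "OK"
  }, character(1))
  out$advisory <- ifelse(out$status == "OK", NA_character_, QC_ADVISORY)
  class(out) <- c("qc_result", class(out))
  out
}

#' Write machine- and human-readable QC reports
#'
#' Writes `report.json` (all metrics plus flags), `report.csv`, and trend
#' plots (`trends.pdf`: doubling time, area and circularity against
#' passage number) into `out_dir`.
#'
#' @param qc a [evaluate_qc()] result (or a bare [passage_profile()],
#'   which is evaluated with default rules).
#' @param out_dir output directory, created if missing.
#' @param rules rules used when `qc` is a bare profile table.
#' @return invisibly, the paths written.
#' @export
write_report <- function(qc, out_dir, rules = qc_rules()) {
  if (!inherits(qc, "qc_result")) qc <- evaluate_qc(qc, rules)
  if (nrow(qc) < 1L) stop("at least one profile is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  json_path <- file.path(out_dir, "report.json")
  csv_path <- file.path(out_dir, "report.csv")
  pdf_path <- file.path(out_dir, "trends.pdf")
  payload <- list(
    profiles = dplyr::select(qc, -dplyr::any_of(c("advisory"))),
    generated_by = paste0("cellmon ", as.character(utils::packageVersion("cellmon")))
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  flat <- qc
  flat$flags <- vapply(flat$flags, paste, character(1), collapse = ";")
  utils::write.csv(flat, csv_path, row.names = FALSE)
  grDevices::pdf(pdf_path, width = 7, height = 8)
  print(plot_passage_trends(qc))
  grDevices::dev.off()
  invisible(c(json = json_path, csv = csv_path, pdf = pdf_path))
}

#' Reload passage profiles from a written report
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return a `qc_result` tibble with the stored metrics, flags and status.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- tibble::as_tibble(payload$profiles)
  p$flags <- lapply(p$flags, function(f) if (is.null(f)) character(0) else as.character(f))
  p$passage_number <- as.integer(p$passage_number)
  p$advisory <- ifelse(p$status == "OK", NA_character_, QC_ADVISORY)
  class(p) <- c("qc_result", class(p))
  p
}
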