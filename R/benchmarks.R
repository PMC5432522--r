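# Ground-truth benchmark suites: every routine regenerates its synthetic
# inputs from scratch, runs the full measurement pipeline, and reports
# per-replicate results against the generator truth. The same code backs
# the acceptance tests and the standalone acceptance script.

#' Counting-exactness benchmark
#'
#' Renders sparse fields (20 cells, hard-core spacing at least three times
#' the texture scale, well under 30% confluency) and checks how often
#' [detect_cells()] recovers the planted count exactly.
#'
#' @param n_fields number of random fields.
#' @param base_seed integer seed; field i uses `base_seed * 1000 + i`.
#' @param n_cells planted cells per field.
#' @return a tibble with one row per field: `seed`, `n_true`, `n_detected`,
#'   `exact`, `confluency`.
#' @export
benchmark_counting <- function(n_fields = 100, base_seed = 1, n_cells = 20) {
  purrr::map_dfr(seq_len(n_fields), function(i) {
    sf <- synth_field(cell_population_spec(n_cells = n_cells,
                                           seed = base_seed * 1000L + i))
    det <- detect_cells(sf$image)
    tibble::tibble(seed = base_seed * 1000L + i,
                   n_true = nrow(sf$truth), n_detected = det$n_cells,
                   exact = det$n_cells == nrow(sf$truth),
                   confluency = confluency(det$mask))
  })
}

#' Morphometric-recovery benchmark
#'
#' Per field: mean measured projected area and circularity of non-border
#' cells against the analytic generator truth.
#'
#' @param n_fields number of random fields.
#' @param base_seed integer seed.
#' @return a tibble with `seed`, `area_ratio` (measured/true mean area) and
#'   `circularity_error` (measured minus true mean circularity).
#' @export
benchmark_morphometrics <- function(n_fields = 50, base_seed = 1) {
  purrr::map_dfr(seq_len(n_fields), function(i) {
    sf <- synth_field(cell_population_spec(n_cells = 20,
                                           seed = base_seed * 1000L + 500L + i))
    rec <- measure_cells(detect_cells(sf$image))
    rec <- rec[!rec$border, ]
    tibble::tibble(seed = base_seed * 1000L + 500L + i,
                   area_ratio = mean(rec$area_um2) / mean(sf$truth$area_um2),
                   circularity_error = mean(rec$circularity) - mean(sf$truth$circularity))
  })
}

#' Doubling-time recovery benchmark
#'
#' Full image -> count -> doubling-time pipeline with Poisson count noise:
#' each replicate simulates a monitored culture sampled every 8 h over
#' 24-72 h of culture at an expected 30 cells per field at the first frame
#' (6-well format seeded to that density), renders every frame, counts
#' cells with [detect_cells()], and fits the log-linear doubling time.
#'
#' @param n_runs number of independent simulated cultures.
#' @param base_seed integer seed.
#' @param doubling_time_h planted ground-truth doubling time.
#' @return a tibble with `seed`, `td_true`, `td_estimate`, `r_squared`.
#' @export
benchmark_doubling_time <- function(n_runs = 50, base_seed = 1,
                                    doubling_time_h = 20) {
  purrr::map_dfr(seq_len(n_runs), function(i) {
    g <- growth_sim_spec(
      n0_cells_per_well = 2.28e5,          # ~30 expected cells per imaged field
      doubling_time_h = doubling_time_h,
      schedule = acquisition_schedule(24, 72, 480, regions = 1, n_passages = 1),
      layout = plate_layout(),
      count_noise = "poisson",
      seed = base_seed * 1000L + i
    )
    tl <- synth_timelapse(g, pop = population_preset("P4", min_gap_um = 6),
                          frame_size_px = c(768L, 768L),
                          pixel_size_x_um = 0.463)
    fit <- doubling_time_loglinear(count_frames(tl))
    tibble::tibble(seed = base_seed * 1000L + i,
                   td_true = doubling_time_h,
                   td_estimate = fit$estimate$doubling_time_h,
                   r_squared = fit$estimate$r_squared)
  })
}

#' Tube-network metrology benchmark
#'
#' Random 2-D and 3-D capsule trees analysed with
#' [skeletonize_mask()]/[graph_from_skeleton()]/[capillary_metrics()]
#' against the generating polyline truth.
#'
#' @param n_2d,n_3d number of 2-D and 3-D networks.
#' @param base_seed integer seed.
#' @return a tibble with `seed`, `dims`, `length_rel_error`,
#'   `branch_true`, `branch_measured`, `branch_exact`.
#' @export
benchmark_networks <- function(n_2d = 25, n_3d = 25, base_seed = 1) {
  run1 <- function(i, dims) {
    nw <- if (dims == "2d") {
      synth_network(n_segments = 10, segment_length_um_range = c(30, 80),
                    tube_radius_um = 5, dims_px = c(300, 300),
                    voxel_size_um = 1, seed = base_seed * 1000L + i)
    } else {
      synth_network(n_segments = 8, segment_length_um_range = c(25, 60),
                    tube_radius_um = 4, dims_px = c(140, 140, 60),
                    voxel_size_um = 1, seed = base_seed * 1000L + 300L + i)
    }
    met <- analyze_network(tube_mask(nw$mask, nw$voxel_size_um))$metrics
    tibble::tibble(
      seed = base_seed * 1000L + if (dims == "2d") i else 300L + i,
      dims = dims,
      length_rel_error = met$total_length_um / nw$truth$total_length_um - 1,
      branch_true = nw$truth$n_branch_points,
      branch_measured = met$n_branch_points,
      branch_exact = met$n_branch_points == nw$truth$n_branch_points
    )
  }
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_2d), run1, dims = "2d"),
    purrr::map_dfr(seq_len(n_3d), run1, dims = "3d")
  )
}

#' Spheroid-dynamics classification benchmark
#'
#' Simulates compacting, dissociating and static microwell series and
#' checks [classify_dynamics()] on the measured tracks.
#'
#' @param n_per_mode series per mode.
#' @param base_seed integer seed.
#' @return a tibble with `seed`, `mode`, `classified`, `correct`.
#' @export
benchmark_spheroids <- function(n_per_mode = 50, base_seed = 1) {
  modes <- c("compacting", "dissociating", "none")
  purrr::map_dfr(modes, function(mode) {
    purrr::map_dfr(seq_len(n_per_mode), function(i) {
      ss <- synth_spheroid_series(mode, seed = base_seed * 1000L + i)
      cl <- classify_dynamics(track_aggregate(ss))
      tibble::tibble(seed = base_seed * 1000L + i, mode = mode,
                     classified = cl, correct = cl == mode)
    })
  })
}
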