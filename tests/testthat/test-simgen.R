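test_that("an empty population renders a blank field", {
  sf <- synth_field(cell_population_spec(n_cells = 0, seed = 1))
  expect_identical(nrow(sf$truth), 0L)
  expect_false(any(sf$mask))
  # background plus noise only
  expect_lt(sd(sf$image$pixels), 5)
  expect_equal(mean(sf$image$pixels), 128, tolerance = 0.05)
})

test_that("generators are bit-identical under a fixed seed", {
  a <- default_field(7)
  b <- default_field(7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)

  n1 <- synth_network(n_segments = 10, seed = 3)
  n2 <- synth_network(n_segments = 10, seed = 3)
  expect_identical(n1$mask, n2$mask)
  expect_identical(n1$truth$total_length_um, n2$truth$total_length_um)

  s1 <- synth_spheroid_series("compacting", seed = 5)
  s2 <- synth_spheroid_series("compacting", seed = 5)
  expect_identical(s1$truth, s2$truth)
})

test_that("rasterized per-cell mask areas match the analytic ellipse areas", {
  sf <- synth_field(cell_population_spec(n_cells = 20, min_gap_um = 10, seed = 2))
  expect_identical(nrow(sf$truth), 20L)
  lab <- cellmon:::label_components(sf$mask)
  expect_identical(max(lab), 20L)
  px_area <- 0.463^2
  st <- cellmon:::label_stats(lab)
  # match rasterized components to truth by centroid
  for (k in seq_len(20)) {
    d <- (st$cx_px * 0.463 - sf$truth$cx_um[k])^2 +
      (st$cy_px * 0.463 - sf$truth$cy_um[k])^2
    j <- which.min(d)
    expect_lt(abs(st$area_px[j] * px_area / sf$truth$area_um2[k] - 1), 0.03)
  }
})

test_that("truth circularity hits the target for degenerate area spread", {
  for (target in c(0.3, 0.6, 0.9, 1)) {
    pop <- cell_population_spec(n_cells = 5, area_um2_sd = 0,
                                circularity_target = target, seed = 4)
    sf <- synth_field(pop)
    expect_true(all(abs(sf$truth$circularity - target) < 0.02))
  }
})

test_that("overfull fields raise a capacity error reporting the shortfall", {
  pop <- cell_population_spec(n_cells = 500, area_um2_mean = 400,
                              min_gap_um = 30, seed = 1)
  expect_error(synth_field(pop, frame_size_px = c(256, 256)),
               "capacity|does not fit")
})

test_that("noiseless expected counts double every doubling time", {
  g <- growth_sim_spec(
    n0_cells_per_well = 3e4, doubling_time_h = 24,
    schedule = acquisition_schedule(24, 72, 60),
    layout = plate_layout(), count_noise = "none", seed = 1
  )
  # frame sized to the full 1.2 x 0.8 mm field: 240 x 160 px at 5 um/px
  tl <- synth_timelapse(g, frame_size_px = c(240L, 160L), pixel_size_x_um = 5,
                        render_frames = FALSE)
  tr <- tl$truth
  expect_equal(tr$expected_count[tr$time_h == 24], 30)
  expect_equal(tr$expected_count[tr$time_h == 48],
               2 * tr$expected_count[tr$time_h == 24])
  # exact doubling relation across the whole noiseless series
  n24 <- tr$expected_count[match(tr$time_h, tr$time_h)]
  shifted <- tr$expected_count[match(tr$time_h + 24, tr$time_h)]
  keep <- !is.na(shifted)
  expect_equal(shifted[keep], 2 * tr$expected_count[keep], tolerance = 1e-12)
})

test_that("a carrying capacity equal to the seed count freezes growth", {
  g <- growth_sim_spec(
    n0_cells_per_well = 3e4, doubling_time_h = 20, carrying_capacity = 3e4,
    schedule = acquisition_schedule(24, 72, 120), count_noise = "none", seed = 1
  )
  tl <- synth_timelapse(g, frame_size_px = c(240L, 160L), pixel_size_x_um = 5,
                        render_frames = FALSE)
  expect_true(all(abs(tl$truth$expected_count - tl$truth$expected_count[1]) < 1e-9))
})

test_that("single-segment networks carry exact truth", {
  nw <- synth_network(n_segments = 1, segment_length_um_range = c(100, 100),
                      tube_radius_um = 5, dims_px = c(256, 256), seed = 2)
  expect_equal(nw$truth$total_length_um, 100)
  expect_identical(nw$truth$n_branch_points, 0L)
  expect_true(any(nw$mask > 0))
})

test_that("spheroid series obey their mode contracts in the ground truth", {
  none <- synth_spheroid_series("none", n_cells = 12, seed = 1)
  expect_true(all(none$truth$n_fragments == 12L))

  comp <- synth_spheroid_series("compacting", seed = 1)
  last <- comp$truth[nrow(comp$truth), ]
  expect_identical(last$n_fragments, 1L)
  expect_gte(last$circularity, 0.9)

  diss <- synth_spheroid_series("dissociating", seed = 1)
  expect_gt(diss$truth$n_fragments[nrow(diss$truth)], diss$truth$n_fragments[1])

  expect_error(synth_spheroid_series("wobbling"), "arg")
  expect_error(synth_spheroid_series("none", n_frames = 1), "n_frames")
})

test_that("microwell grid images carry exact centre truth", {
  g <- synth_microwell_grid(n_rows = 2, n_cols = 4, seed = 9)
  expect_identical(nrow(g$truth), 8L)
  expect_s3_class(g$image, "cellmon_image")
})
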