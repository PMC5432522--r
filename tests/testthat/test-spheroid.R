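test_that("microwell grids are detected with sub-pitch accuracy", {
  g <- synth_microwell_grid(n_rows = 3, n_cols = 3, seed = 1)
  det <- detect_grid(g$image)
  expect_identical(det$n_detected, 9L)
  d <- sqrt(outer(det$centers$cx_px, g$truth$cx_px, "-")^2 +
              outer(det$centers$cy_px, g$truth$cy_px, "-")^2)
  expect_true(all(apply(d, 2, min) <= 5))
})

test_that("grid detection is equivariant under integer translation", {
  g0 <- synth_microwell_grid(n_rows = 3, n_cols = 3, seed = 2)
  g1 <- synth_microwell_grid(n_rows = 3, n_cols = 3, seed = 2,
                             offset_px = c(40L, 25L))
  c0 <- detect_grid(g0$image)$centers
  c1 <- detect_grid(g1$image)$centers
  expect_identical(nrow(c0), nrow(c1))
  expect_equal(sort(c1$cx_px), sort(c0$cx_px + 40), tolerance = 0.2)
  expect_equal(sort(c1$cy_px), sort(c0$cy_px + 25), tolerance = 0.2)
})

test_that("a blank chip image raises a detection error", {
  set.seed(3)
  blank <- calibrated_image(
    cellmon:::clip255(matrix(160 + rnorm(400 * 400, sd = 3), 400, 400)), 3)
  expect_error(detect_grid(blank), "no microwell pattern")
  tiny <- calibrated_image(matrix(160, 40, 40), 3)
  expect_error(detect_grid(tiny), "span")
})

test_that("aggregate tracks follow the generator dynamics", {
  comp <- track_aggregate(synth_spheroid_series("compacting", seed = 11))
  expect_identical(comp$n_fragments[nrow(comp)], 1L)
  expect_gte(comp$circularity[nrow(comp)], 0.8)

  diss <- track_aggregate(synth_spheroid_series("dissociating", seed = 11))
  expect_gt(diss$n_fragments[nrow(diss)], min(diss$n_fragments))
  expect_s3_class(autoplot(comp), "ggplot")
})

test_that("empty wells track zero area throughout", {
  blank <- lapply(1:3, function(i) {
    sf <- synth_field(cell_population_spec(n_cells = 0, seed = i),
                      frame_size_px = c(300, 300), pixel_size_x_um = 2)
    img <- sf$image
    img$time_h <- 3 * i
    img
  })
  tr <- track_aggregate(blank)
  expect_true(all(tr$area_um2 <= 300))   # at most segmentation-noise specks
  expect_true(all(tr$n_fragments <= 1L))
})

test_that("dynamics classification matches the planted mode", {
  for (mode in c("compacting", "dissociating", "none")) {
    for (s in 1:5) {
      tr <- track_aggregate(synth_spheroid_series(mode, seed = s))
      expect_identical(classify_dynamics(tr), mode)
    }
  }
})

test_that("classification validates its inputs", {
  short <- tibble::tibble(time_h = 1:2, area_um2 = c(1, 1),
                          circularity = c(0.5, 0.5), n_fragments = c(1L, 1L))
  expect_error(classify_dynamics(short), "at least 3")
})

test_that("a compacted spheroid's equivalent diameter matches its true size", {
  tr <- track_aggregate(synth_spheroid_series("compacting",
                                              spheroid_diameter_um = 200,
                                              seed = 4))
  expect_equal(final_equivalent_diameter(tr), 200, tolerance = 0.05)
})
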