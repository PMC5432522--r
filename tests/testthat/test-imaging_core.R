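test_that("calibrated images validate their invariants", {
  expect_error(calibrated_image(matrix(300, 2, 2)), "within \\[0, 255\\]")
  expect_error(calibrated_image(matrix(10, 2, 2), pixel_size_x_um = 0),
               "strictly positive")
  expect_error(calibrated_image(array(1, c(3, 3, 3))), "matrix")
  img <- calibrated_image(matrix(128, 4, 5), 0.463)
  expect_s3_class(img, "cellmon_image")
  expect_equal(dim(img), c(4, 5))
  expect_equal(pixel_area_um2(img), 0.463^2)
})

test_that("8-bit TIFF save/load round-trips pixel data exactly", {
  set.seed(11)
  px <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  img <- calibrated_image(px, 0.463)
  path <- withr::local_tempfile(fileext = ".tif")
  save_image(img, path)
  back <- load_image(path, pixel_size_x_um = 0.463)
  expect_identical(back$pixels, px + 0)
  expect_equal(dim(back), c(100, 100))
})

test_that("16-bit input is rescaled so the representable maximum is 255", {
  px16 <- matrix(c(0, 0.25, 0.5, 1), 2, 2)     # 16-bit TIFF carries [0,1]
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px16, path, bits.per.sample = 16L)
  img <- load_image(path)
  expect_equal(max(img$pixels), 255)
  expect_equal(min(img$pixels), 0)
})

test_that("multi-channel input is rejected with the offending shape", {
  rgb <- array(runif(12), c(2, 2, 3))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, path)
  expect_error(load_image(path), "2, 2, 3")
  expect_error(load_image("no/such/file.tif"), "no such file")
})

test_that("regions per plate multiplies wells by regions", {
  expect_identical(regions_per_plate(plate_layout()), 30L)
  expect_identical(regions_per_plate(
    plate_layout(n_rows = 1, n_cols = 1, regions_per_well = 1)), 1L)
  expect_identical(regions_per_plate(
    plate_layout(n_rows = 4, n_cols = 6, regions_per_well = 3)), 72L)
})

test_that("regions_per_plate is monotone in every layout field", {
  base <- plate_layout(n_rows = 2, n_cols = 3, regions_per_well = 4)
  r0 <- regions_per_plate(base)
  expect_gte(regions_per_plate(plate_layout(n_rows = 3, n_cols = 3, regions_per_well = 4)), r0)
  expect_gte(regions_per_plate(plate_layout(n_rows = 2, n_cols = 4, regions_per_well = 4)), r0)
  expect_gte(regions_per_plate(plate_layout(n_rows = 2, n_cols = 3, regions_per_well = 5)), r0)
})

test_that("schedule planning uses the half-open window", {
  sch <- acquisition_schedule(24, 72, 60, regions = 10, n_passages = 12)
  ev <- plan_schedule(sch)
  expect_identical(nrow(ev), 5760L)
  expect_identical(total_image_count(sch), 5760L)
  expect_equal(range(ev$time_h), c(24, 71))

  expect_identical(nrow(plan_schedule(acquisition_schedule(0, 1, 60, 1, 1))), 1L)
  expect_identical(nrow(plan_schedule(acquisition_schedule(24, 72, 30, 1, 1))), 96L)
  expect_error(acquisition_schedule(72, 24), "end_h > start_h")
  expect_error(acquisition_schedule(0, 1, interval_min = 0), "positive")
})

test_that("event count equals the planned total for random schedules", {
  set.seed(42)
  for (i in 1:20) {
    sch <- acquisition_schedule(
      start_h = runif(1, 0, 48),
      end_h = runif(1, 49, 120),
      interval_min = sample(c(15, 30, 60, 90, 120), 1),
      regions = sample(1:30, 1),
      n_passages = sample(1:12, 1)
    )
    expect_identical(nrow(plan_schedule(sch)), as.integer(total_image_count(sch)))
  }
})

test_that("YAML run configuration round-trips layout and schedule", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "layout:",
    "  n_rows: 4",
    "  n_cols: 6",
    "  regions_per_well: 3",
    "schedule:",
    "  start_h: 12",
    "  end_h: 36",
    "  interval_min: 30"
  ), path)
  cfg <- read_run_config(path)
  expect_identical(regions_per_plate(cfg$layout), 72L)
  expect_identical(frames_per_region(cfg$schedule), 48L)
})

test_that("manifests require the standard columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(path = "a.tif", plate = "P1", well_row = 0,
                       well_col = 0, region = 0, time_h = 24),
            path, row.names = FALSE)
  m <- read_manifest(path)
  expect_identical(nrow(m), 1L)
  expect_true(grepl("a\\.tif$", m$path))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(path = "a.tif"), bad, row.names = FALSE)
  expect_error(read_manifest(bad), "missing column")
})
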