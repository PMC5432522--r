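test_that("flattening leaves a uniform image unchanged", {
  img <- calibrated_image(matrix(140, 256, 256), 0.463)
  out <- flatten_background(img)
  expect_true(all(abs(out$pixels - img$pixels) <= 1))
})

test_that("flattening removes a linear luminance ramp", {
  ramp <- matrix(rep(seq(100, 140, length.out = 256), each = 256), 256, 256,
                 byrow = TRUE)
  img <- calibrated_image(ramp, 0.463)
  out <- flatten_background(img)
  resid <- apply(out$pixels, 2, median)
  expect_lt(diff(range(resid)), 4)
})

test_that("flattening suppresses synthetic vignetting", {
  sf <- synth_field(cell_population_spec(n_cells = 10, seed = 3),
                    render = relief_render_spec(vignette_strength = 0.3,
                                                noise_sd = 1))
  corner_centre_gap <- function(px) {
    abs(median(px[1:40, 1:40]) - median(px[236:276, 236:276]))
  }
  before <- corner_centre_gap(sf$image$pixels)
  after <- corner_centre_gap(flatten_background(sf$image)$pixels)
  expect_gt(before / after, 5)
})

test_that("texture energy is zero on constant input and 90-degree equivariant", {
  img <- calibrated_image(matrix(128, 128, 128), 1)
  expect_true(all(unclass(texture_energy(img)) == 0))

  sf <- default_field(5)
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  e <- strip(texture_energy(flatten_background(sf$image), 1))
  rot90 <- function(m) t(m)[, nrow(m):1]
  img_r <- calibrated_image(rot90(flatten_background(sf$image)$pixels), 0.463)
  e_r <- strip(texture_energy(img_r, 1))
  expect_equal(e_r, rot90(e), tolerance = 1e-8)
})

test_that("texture energy peaks inside a cell's true support", {
  sf <- synth_field(cell_population_spec(n_cells = 1, seed = 8))
  e <- unclass(texture_energy(flatten_background(sf$image), 1))
  expect_true(sf$mask[which.max(e)])
})

test_that("binarize handles blank fields and degenerate maps", {
  blank <- synth_field(cell_population_spec(n_cells = 0, seed = 1))
  mask <- binarize(texture_energy(flatten_background(blank$image), 1))
  expect_identical(sum(unclass(mask)), 0L)

  const <- as_map(matrix(3, 64, 64))
  m2 <- binarize(const)
  expect_true(attr(m2, "degenerate"))
  expect_identical(sum(unclass(m2)), 0L)
})

test_that("a high-energy plateau binarizes to all-foreground minus border effects", {
  m <- matrix(0.1, 96, 96)
  m[9:88, 9:88] <- 10
  mask <- binarize(as_map(m), segmentation_params(threshold_method = "otsu",
                                                  refine_fraction = NULL))
  inner <- unclass(mask)[12:85, 12:85]
  expect_true(all(inner == 1))
})

test_that("binarized masks overlap the generator truth", {
  sf <- default_field(1)
  flat <- flatten_background(sf$image)
  mask <- binarize(texture_energy(flat, 1), segmentation_params(),
                   refine_map = texture_energy(flat, 0.4))
  iou <- sum(mask == 1 & sf$mask) / sum(mask == 1 | sf$mask)
  expect_gte(iou, 0.6)
})

test_that("well-separated cells are counted exactly with accurate centroids", {
  sf <- synth_field(cell_population_spec(n_cells = 20, min_gap_um = 15, seed = 12))
  det <- detect_cells(sf$image)
  expect_identical(det$n_cells, 20L)
  d <- sqrt(outer(det$cells$cx_px * 0.463, sf$truth$cx_um, "-")^2 +
              outer(det$cells$cy_px * 0.463, sf$truth$cy_um, "-")^2)
  err_px <- apply(d, 2, min) / 0.463
  expect_lt(mean(err_px), 2)
})

test_that("blank fields yield zero cells", {
  blank <- synth_field(cell_population_spec(n_cells = 0, seed = 2))
  det <- detect_cells(blank$image)
  expect_identical(det$n_cells, 0L)
  expect_identical(nrow(measure_cells(det)), 0L)
})

test_that("touching cells split under the watershed and merge without it", {
  pop <- cell_population_spec(n_cells = 2, area_um2_mean = 400, area_um2_sd = 0,
                              circularity_target = 1, seed = 7)
  r <- sqrt(400 / pi)
  pos <- rbind(c(100, 100), c(100 + 2.05 * r, 100))
  sf <- synth_field(pop, positions_um = pos)
  with_split <- detect_cells(sf$image, segmentation_params(split_touching = TRUE))
  no_split <- detect_cells(sf$image, segmentation_params(split_touching = FALSE))
  expect_identical(with_split$n_cells, 2L)
  expect_identical(no_split$n_cells, 1L)
})

test_that("adding a distant cell never decreases the count", {
  for (s in 1:5) {
    pop10 <- cell_population_spec(n_cells = 10, area_um2_sd = 0, seed = s)
    sf10 <- synth_field(pop10)
    # same geometry plus one far-away cell: re-render with explicit positions
    geom <- sf10$truth
    pos <- cbind(geom$cx_um, geom$cy_um)
    far <- c(12, 12)  # top-left corner, min_gap away from everything by construction
    pop11 <- cell_population_spec(n_cells = 11, area_um2_sd = 0, seed = s)
    sf11 <- synth_field(pop11, positions_um = rbind(far, pos))
    n10 <- detect_cells(sf10$image)$n_cells
    n11 <- detect_cells(sf11$image)$n_cells
    expect_gte(n11, n10)
  }
})

test_that("confluency is exact pixel arithmetic and symmetry invariant", {
  m <- matrix(0L, 100, 100)
  expect_identical(confluency(m), 0)
  expect_identical(confluency(m + 1L), 1)
  m[1:50, 1:50] <- 1L
  expect_identical(confluency(m), 0.25)
  expect_identical(confluency(t(m)), 0.25)
  expect_identical(confluency(m[100:1, ]), 0.25)
  expect_identical(confluency(m[, 100:1]), 0.25)
})

test_that("confluency stays within [0, 1] on segmented fields", {
  for (s in 1:3) {
    det <- detect_cells(default_field(s)$image)
    cf <- confluency(det$mask)
    expect_gte(cf, 0)
    expect_lte(cf, 1)
  }
})
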