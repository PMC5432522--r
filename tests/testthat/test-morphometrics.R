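test_that("a rasterized disc measures as a near-perfect circle", {
  m <- disc_mask(50)
  p <- crofton_perimeter(m, 1, 1)
  a <- sum(m)
  circ <- min(4 * pi * a / p^2, 1)
  expect_gte(circ, 0.95)
  expect_lte(circ, 1)
  # Crofton perimeter itself is close to 2*pi*r
  expect_equal(p, 2 * pi * 50, tolerance = 0.02)
})

test_that("a 4:1 ellipse has the closed-form circularity", {
  m <- ellipse_mask(40, 10)
  p <- crofton_perimeter(m, 1, 1)
  a <- sum(m)
  circ <- 4 * pi * a / p^2
  # oracle: 4*pi*(pi*a*b) / P_ramanujan^2
  p_ram <- pi * (3 * (40 + 10) - sqrt((3 * 40 + 10) * (40 + 3 * 10)))
  oracle <- 4 * pi * (pi * 40 * 10) / p_ram^2
  expect_equal(oracle, 0.536, tolerance = 0.002)
  expect_equal(circ, oracle, tolerance = 0.03)
})

test_that("circularity is clamped at 1 with the raw value retained", {
  lab <- matrix(0L, 9, 9); lab[5, 5] <- 1L
  rec <- measure_cells(as_labels(lab))
  expect_identical(rec$circularity, 1)
  expect_gt(rec$circularity_raw, 1)
  expect_gt(rec$area_um2, 0)
})

test_that("profile classification matches the passage archetypes", {
  th <- profile_thresholds()
  expect_identical(as.character(classify_profile(80, th, 0.8)), "round_small")
  expect_identical(as.character(classify_profile(330, th, 0.7)), "round_large")
  expect_identical(as.character(classify_profile(60, th, 0.3)), "nonround_small")
  expect_identical(as.character(classify_profile(300, th, 0.2)), "nonround_large")
  # ties go to the small / round side
  expect_identical(as.character(classify_profile(150, th, 0.5)), "round_small")
})

test_that("summaries use the sample SD convention and honour border flags", {
  one <- tibble::tibble(area_um2 = 120, circularity = 0.7, border = FALSE)
  s1 <- summarize_morphology(one)
  expect_identical(s1$n, 1L)
  expect_identical(s1$area_sd, 0)
  expect_identical(s1$area_mean, 120)

  two <- tibble::tibble(area_um2 = c(100, 200), circularity = c(0.6, 0.8),
                        border = FALSE)
  s2 <- summarize_morphology(two)
  expect_equal(s2$area_mean, 150)
  expect_equal(s2$area_sd, sd(c(100, 200)))   # 70.71, n-1 denominator

  allb <- tibble::tibble(area_um2 = c(100, 200), circularity = c(0.6, 0.8),
                         border = TRUE)
  s3 <- summarize_morphology(allb)
  expect_identical(s3$n, 0L)
  expect_true(is.na(s3$area_mean))
})

test_that("measurements are covariant under pixel-size rescaling", {
  lab <- ellipse_mask(30, 15)
  r1 <- measure_cells(as_labels(lab, 1))
  r2 <- measure_cells(as_labels(lab, 2))
  expect_equal(r2$perimeter_um, 2 * r1$perimeter_um)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  expect_equal(r2$circularity, r1$circularity, tolerance = 0.02)
})

test_that("mean area and circularity recover the generator truth", {
  arat <- dcirc <- numeric(0)
  for (s in 1:8) {
    sf <- default_field(s)
    rec <- measure_cells(detect_cells(sf$image))
    rec <- rec[!rec$border, ]
    arat <- c(arat, mean(rec$area_um2) / mean(sf$truth$area_um2))
    dcirc <- c(dcirc, mean(rec$circularity) - mean(sf$truth$circularity))
  }
  expect_lt(abs(mean(arat) - 1), 0.05)
  expect_lt(abs(mean(dcirc)), 0.05)
})
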