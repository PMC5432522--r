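test_that("well counts scale region means by the area ratio", {
  layout <- plate_layout()   # 960 mm2 well, 0.96 mm2 field: ratio 1000
  expect_equal(well_count_from_regions(rep(30, 5), layout), 30000)
  expect_equal(well_count_from_regions(0, layout), 0)
  expect_equal(well_count_from_regions(c(10, 20), layout), 15000)
  expect_error(well_count_from_regions(numeric(0), layout), "at least one")
})

test_that("endpoint doubling time follows the closed form", {
  expect_equal(doubling_time_endpoint(1000, 24, 2000, 48)$doubling_time_h, 24)
  expect_equal(doubling_time_endpoint(3e4, 24, 1.2e5, 72)$doubling_time_h, 24)
  est <- doubling_time_endpoint(1000, 24, 5278, 72)
  expect_equal(est$doubling_time_h, 48 * log(2) / log(5.278), tolerance = 1e-12)
  expect_equal(est$doubling_time_h, 20, tolerance = 0.01)
})

test_that("endpoint estimator flags non-growth instead of erroring", {
  est <- doubling_time_endpoint(2000, 24, 1500, 72)
  expect_false(est$growth)
  expect_true(is.na(est$doubling_time_h))
  # swapping the endpoints of a growing pair lands in the non-growth branch
  expect_false(doubling_time_endpoint(2000, 24, 1000, 48)$growth)
  expect_error(doubling_time_endpoint(0, 24, 100, 48), "positive")
  expect_error(doubling_time_endpoint(10, 48, 100, 24), "t2_h > t1_h")
})

test_that("endpoint doubling time is invariant to common count rescaling", {
  a <- doubling_time_endpoint(1000, 24, 3100, 60)$doubling_time_h
  b <- doubling_time_endpoint(7000, 24, 21700, 60)$doubling_time_h
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("log-linear fit is exact on noiseless exponentials", {
  t <- 24:72
  series <- tibble::tibble(time_h = t, count = 1000 * 2^((t - 24) / 20))
  fit <- doubling_time_loglinear(series)
  expect_equal(fit$estimate$doubling_time_h, 20, tolerance = 1e-6)
  expect_equal(fit$estimate$r_squared, 1, tolerance = 1e-12)
  # agreement with the endpoint formula on the same data
  ep <- doubling_time_endpoint(series$count[1], 24, series$count[49], 72)
  expect_equal(fit$estimate$doubling_time_h, ep$doubling_time_h, tolerance = 1e-6)
})

test_that("log-linear fit flags constant series and names bad points", {
  const <- tibble::tibble(time_h = c(24, 48, 72), count = c(500, 500, 500))
  expect_false(doubling_time_loglinear(const)$estimate$growth)
  bad <- tibble::tibble(time_h = c(24, 48, 72), count = c(500, 0, 700))
  expect_error(doubling_time_loglinear(bad), "48")
  expect_error(doubling_time_loglinear(const[1:2, ]), "at least 3")
})

test_that("growth_fit exposes broom-style verbs and plots", {
  t <- seq(24, 72, by = 4)
  fit <- doubling_time_loglinear(tibble::tibble(time_h = t, count = 30 * 2^((t - 24) / 20)))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "time_h"))
  g <- glance(fit)
  expect_equal(g$doubling_time_h, 20, tolerance = 1e-6)
  expect_identical(g$n, length(t))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("count comparison reproduces the normal-equations slope", {
  ident <- tibble::tibble(automated = c(100, 200, 300), manual = c(100, 200, 300))
  ci <- compare_counts(ident)
  expect_equal(ci$slope, 1)
  expect_equal(ci$r_squared, 1)

  prop <- tibble::tibble(automated = c(100, 250, 420), manual = 0.9 * c(100, 250, 420))
  cp <- compare_counts(prop)
  expect_equal(cp$slope, 0.9, tolerance = 1e-12)
  expect_equal(cp$r_squared, 1, tolerance = 1e-12)

  set.seed(31)
  x <- runif(25, 50, 500)
  y <- 0.9 * x + rnorm(25, sd = 20)
  y <- pmax(y, 1)
  cc <- compare_counts(tibble::tibble(automated = x, manual = y))
  expect_equal(cc$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_s3_class(autoplot(cc), "ggplot")

  expect_error(compare_counts(ident[1, ]), "at least 2")
  expect_error(compare_counts(tibble::tibble(automated = c(-1, 2), manual = c(1, 2))),
               "positive")
})

test_that("growth series aggregate regions into per-well curves", {
  df <- tibble::tibble(time_h = rep(c(24, 48), each = 5),
                       count = c(rep(30, 5), rep(60, 5)))
  gs <- growth_series(df, plate_layout())
  expect_identical(nrow(gs), 2L)
  expect_equal(gs$count_per_well, c(30000, 60000))
  expect_identical(gs$n_regions, c(5L, 5L))
  expect_s3_class(autoplot(gs), "ggplot")
})

test_that("the rendered pipeline recovers counts frame by frame", {
  g <- growth_sim_spec(
    n0_cells_per_well = 2.28e5, doubling_time_h = 20,
    schedule = acquisition_schedule(24, 72, 24 * 60),
    layout = plate_layout(), count_noise = "none", seed = 5
  )
  tl <- synth_timelapse(g, pop = population_preset("P4", min_gap_um = 8),
                        frame_size_px = c(512L, 512L), pixel_size_x_um = 0.463)
  counts <- count_frames(tl)
  expect_identical(counts$count, tl$truth$n_cells)
})
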