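paper_rules <- qc_rules(td_band_h = c(16, 26), area_band_um2 = c(70, 200),
                        circularity_min = 0.5)

test_that("QC flags reproduce the passage archetypes", {
  prof <- passage_profile(
    passage_number = c(4, 8, 15),
    doubling_time_h = c(20, 31, 16),
    area_mean_um2 = c(80, 330, 60),
    circularity_mean = c(0.8, 0.6, 0.3)
  )
  qc <- evaluate_qc(prof, paper_rules)
  expect_identical(qc$status, c("OK", "SENESCENCE_SUSPECT", "TRANSFORMATION_SUSPECT"))
  expect_identical(qc$flags[[1]], character(0))
  expect_true(is.na(qc$advisory[1]))
  expect_false(is.na(qc$advisory[2]))
})

test_that("a transformation flag needs all three conditions", {
  # fast and small but still round: no flag
  prof <- passage_profile(10, 15, 60, 0.7)
  expect_identical(evaluate_qc(prof, paper_rules)$status, "OK")
  # slow but small: no senescence flag
  prof2 <- passage_profile(10, 31, 90, 0.7)
  expect_identical(evaluate_qc(prof2, paper_rules)$status, "OK")
})

test_that("missing metrics are rejected by name", {
  prof <- passage_profile(4, NA_real_, 80, 0.8)
  expect_error(evaluate_qc(prof), "doubling_time_h")
  expect_error(evaluate_qc(data.frame(passage_number = 1)), "doubling_time_h")
})

test_that("flag logic is a pure function of profile and rules", {
  prof <- passage_profile(8, 31, 330, 0.6)
  a <- evaluate_qc(prof, paper_rules)
  b <- evaluate_qc(prof, paper_rules)
  expect_identical(a$flags, b$flags)
  expect_identical(a$status, b$status)
})

test_that("raising the circularity floor never removes a transformation flag", {
  prof <- passage_profile(15, 14, 55, 0.35)
  for (lo in seq(0.36, 0.9, by = 0.06)) {
    rules_lo <- qc_rules(circularity_min = lo)
    flagged_lo <- "TRANSFORMATION_SUSPECT" %in% evaluate_qc(prof, rules_lo)$flags[[1]]
    expect_true(flagged_lo)
  }
  # and below the observed circularity the flag is absent
  rules_below <- qc_rules(circularity_min = 0.2)
  expect_identical(evaluate_qc(prof, rules_below)$status, "OK")
})

test_that("a passage sweep transitions OK -> senescent -> transformed", {
  # trajectory mirroring the printed anchors: healthy start, doubling time
  # and size peak mid-sweep, then a fast small spindle-shaped regime
  passages <- 4:15
  td <- c(20, 22, 25, 28, 31, 28, 25, 22, 19, 17, 16, 16)
  area <- c(80, 120, 200, 280, 330, 260, 180, 120, 90, 70, 62, 60)
  circ <- c(0.80, 0.76, 0.72, 0.68, 0.64, 0.60, 0.55, 0.50, 0.46, 0.42, 0.38, 0.30)
  prof <- passage_profile(passages, td, area, circ)
  qc <- evaluate_qc(prof, paper_rules)
  expect_identical(qc$status[1], "OK")
  expect_true("SENESCENCE_SUSPECT" %in% unlist(qc$flags[4:6]))
  expect_identical(qc$status[12], "TRANSFORMATION_SUSPECT")
  # flags appear in the expected order along the sweep
  first_sen <- min(which(vapply(qc$flags, function(f) "SENESCENCE_SUSPECT" %in% f, TRUE)))
  first_tra <- min(which(vapply(qc$flags, function(f) "TRANSFORMATION_SUSPECT" %in% f, TRUE)))
  expect_lt(first_sen, first_tra)
})

test_that("reports round-trip through JSON and CSV", {
  prof <- passage_profile(c(4, 8), c(20, 31), c(80, 330), c(0.8, 0.6),
                          confluency_final = c(0.4, 0.55))
  qc <- evaluate_qc(prof, paper_rules)
  out <- withr::local_tempdir()
  paths <- write_report(qc, out)
  expect_true(file.exists(paths[["json"]]))
  expect_true(file.exists(paths[["csv"]]))
  expect_true(file.exists(paths[["pdf"]]))
  back <- read_report(paths[["json"]])
  expect_equal(back$passage_number, qc$passage_number)
  expect_equal(back$doubling_time_h, qc$doubling_time_h)
  expect_equal(back$area_mean_um2, qc$area_mean_um2)
  expect_identical(back$status, qc$status)
  expect_identical(back$flags, qc$flags)
  expect_s3_class(plot_passage_trends(qc), "ggplot")
})

test_that("the command-line interface segments an image end to end", {
  sf <- default_field(3)
  dir <- withr::local_tempdir()
  img_path <- file.path(dir, "field.tif")
  save_image(sf$image, img_path)
  cli <- system.file("cli", "cellmon.R", package = "cellmon")
  out <- system2("Rscript", c(cli, "segment", "--in", img_path, "--out", dir,
                              "--pixel-size", "0.463"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "cells.csv")))
  expect_true(file.exists(file.path(dir, "mask.png")))
  cells <- read.csv(file.path(dir, "cells.csv"))
  expect_identical(nrow(cells), 20L)
})
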