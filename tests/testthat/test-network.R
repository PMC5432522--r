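test_that("a filled bar thins to a single medial path of the right length", {
  bar <- matrix(0L, 40, 220)
  bar[18:22, 11:210] <- 1L
  sk <- skeletonize_mask(tube_mask(bar, 0.463))
  g <- graph_from_skeleton(sk, c(0.463, 0.463), mask = bar)
  m <- capillary_metrics(g)
  expect_identical(m$n_edges, 1L)
  expect_identical(m$n_branch_points, 0L)
  expect_identical(m$n_endpoints, 2L)
  expect_equal(m$total_length_um, 199 * 0.463, tolerance = 0.03)
  # essentially one voxel wide: about one skeleton voxel per bar column
  expect_lt(sum(sk), 215)
})

test_that("empty masks yield empty skeletons and all-zero metrics", {
  empty <- matrix(0L, 32, 32)
  sk <- skeletonize_mask(tube_mask(empty, 1))
  expect_identical(sum(sk), 0L)
  m <- capillary_metrics(graph_from_skeleton(sk, c(1, 1)))
  expect_identical(m$total_length_um, 0)
  expect_identical(m$n_branch_points, 0L)
  expect_identical(m$n_components, 0L)
})

test_that("a Y junction resolves to three edges and one branch point", {
  ctr <- c(110, 110)
  segs <- lapply(c(90, 210, 330) * pi / 180, function(a) {
    list(from = ctr, to = ctr + 50 * c(cos(a), sin(a)))
  })
  y <- capsules(segs, c(220, 220), 1, 5)
  an <- analyze_network(tube_mask(y, 1))
  expect_identical(an$metrics$n_branch_points, 1L)
  expect_identical(an$metrics$n_edges, 3L)
  expect_identical(an$metrics$n_endpoints, 3L)
  expect_equal(an$metrics$total_length_um, 150, tolerance = 0.05)
  # Euler relation for a tree: endpoints + branches = edges + 1
  expect_identical(an$metrics$n_endpoints + an$metrics$n_branch_points,
                   an$metrics$n_edges + 1L)
})

test_that("an isolated voxel is a single endpoint node without edges", {
  m <- matrix(0L, 21, 21); m[11, 11] <- 1L
  sk <- skeletonize_mask(tube_mask(m, 1))
  g <- graph_from_skeleton(sk, c(1, 1))
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(g$nodes$kind, "endpoint")
  expect_identical(nrow(g$edges), 0L)
  met <- capillary_metrics(g)
  expect_identical(met$n_isolated, 1L)
})

test_that("skeletonization preserves the number of connected components", {
  set.seed(5)
  for (s in 1:4) {
    nw <- synth_network(n_segments = 6, dims_px = c(220, 220), seed = s)
    # add two isolated blobs ("single cell dots")
    m <- nw$mask
    m[20:24, 20:24] <- 1L
    m[200:204, 200:204] <- 1L
    sk <- skeletonize_mask(tube_mask(m, 1))
    # components counted on the 26-connected voxel graph (the skeleton is
    # mostly diagonal, so 4-connected labelling would overcount)
    n_in <- capillary_metrics(graph_from_skeleton(
      skeletonize_mask(tube_mask(m, 1)), c(1, 1), spur_min_voxels = 0))$n_components
    n_out <- capillary_metrics(graph_from_skeleton(sk, c(1, 1), mask = m))$n_components
    expect_identical(n_out, 3L)
    expect_identical(n_in, 3L)
  }
})

test_that("random 2-D networks recover truth lengths and exact branch counts", {
  errs <- numeric(0); exact <- 0L
  for (s in 1:10) {
    nw <- synth_network(n_segments = 10, segment_length_um_range = c(30, 80),
                        tube_radius_um = 5, dims_px = c(300, 300),
                        voxel_size_um = 1, seed = s)
    met <- analyze_network(tube_mask(nw$mask, nw$voxel_size_um))$metrics
    errs <- c(errs, abs(met$total_length_um / nw$truth$total_length_um - 1))
    exact <- exact + (met$n_branch_points == nw$truth$n_branch_points)
    # tree topology: per-component Euler relation
    g <- analyze_network(tube_mask(nw$mask, nw$voxel_size_um))$graph
    for (comp in unique(g$nodes$component)) {
      nn <- sum(g$nodes$component == comp)
      ne <- sum(g$edges$component == comp)
      expect_identical(nn, ne + 1L)
    }
  }
  expect_lte(median(errs), 0.05)
  expect_identical(exact, 10L)
})

test_that("3-D networks are measured through the same code path", {
  errs <- numeric(0); exact <- 0L
  for (s in 1:3) {
    nw <- synth_network(n_segments = 8, segment_length_um_range = c(25, 60),
                        tube_radius_um = 4, dims_px = c(140, 140, 60),
                        voxel_size_um = 1, seed = s)
    met <- analyze_network(tube_mask(nw$mask, nw$voxel_size_um))$metrics
    errs <- c(errs, abs(met$total_length_um / nw$truth$total_length_um - 1))
    exact <- exact + (met$n_branch_points == nw$truth$n_branch_points)
  }
  expect_lte(median(errs), 0.05)
  expect_identical(exact, 3L)
})

test_that("anisotropic voxels scale lengths correctly", {
  # straight tube along z in a (1, 1, 2) um grid: 40 slices of radius 4
  segs <- list(list(from = c(30, 30, 10), to = c(30, 30, 90)))
  m <- capsules(segs, c(60, 60, 50), c(1, 1, 2), 4)
  an <- analyze_network(tube_mask(m, c(1, 1, 2)))
  expect_equal(an$metrics$total_length_um, 80, tolerance = 0.08)
})

test_that("total length is stable under pre-rasterization rotation", {
  base <- list(
    list(from = c(-60, 0), to = c(60, 0)),
    list(from = c(0, 0), to = c(0, 70))
  )
  total <- function(angle) {
    rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
    segs <- lapply(base, function(s) {
      list(from = as.vector(rot %*% s$from) + 110,
           to = as.vector(rot %*% s$to) + 110)
    })
    m <- capsules(segs, c(220, 220), 1, 5)
    analyze_network(tube_mask(m, 1))$metrics$total_length_um
  }
  l0 <- total(0)
  l45 <- total(pi / 4)
  expect_lt(abs(l45 / l0 - 1), 0.05)
})

test_that("grayscale stacks are Otsu-binarized before skeletonization", {
  bar <- matrix(20, 40, 160)
  bar[16:24, 21:140] <- 200
  bar <- bar + matrix(rnorm(40 * 160, sd = 2), 40, 160)
  tm <- tube_mask(bar, 1)
  expect_true(all(tm$mask %in% c(0L, 1L)))
  an <- analyze_network(tm)
  # the bar has flat (not rounded) ends, where the medial axis genuinely
  # stops about half a width short of the end faces
  expect_equal(an$metrics$total_length_um, 120, tolerance = 0.08)
})
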