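#' Cell population specification for the field simulator
#'
#' Cells are modelled as ellipses with lognormally distributed projected
#' area and a target shape circularity that fixes the axis ratio through
#' the Ramanujan perimeter approximation. A hard-core spacing keeps
#' generated cells separated by at least `min_gap_um` (boundary to
#' boundary, conservatively enforced through the semi-major axes).
#'
#' Presets mirror the morphological regimes observed across endothelial
#' passage culture: `"P4"` (round and small, ~80 um2), `"P8"` (round and
#' large, ~330 um2) and `"P15"` (non-round and small, ~60 um2).
#'
#' @param n_cells target number of cells (>= 0).
#' @param area_um2_mean,area_um2_sd mean and SD of the lognormal projected
#'   area, um2.
#' @param circularity_target mean shape circularity in (0, 1].
#' @param min_gap_um hard-core boundary spacing in um (0 permits touching).
#' @param seed RNG seed (`NULL` for the session RNG stream).
#' @return an object of class `cell_population_spec`.
#' @export
cell_population_spec <- function(n_cells = 20L,
                                 area_um2_mean = 200,
                                 area_um2_sd = 50,
                                 circularity_target = 0.75,
                                 min_gap_um = 12,
                                 seed = NULL) {
  stopifnot(n_cells >= 0, area_um2_mean > 0, area_um2_sd >= 0,
            circularity_target > 0, circularity_target <= 1, min_gap_um >= 0)
  structure(
    list(n_cells = as.integer(n_cells),
         area_um2_mean = area_um2_mean, area_um2_sd = area_um2_sd,
         circularity_target = circularity_target,
         min_gap_um = min_gap_um, seed = seed),
    class = "cell_population_spec"
  )
}

#' @rdname cell_population_spec
#' @param preset one of `"P4"`, `"P8"`, `"P15"`.
#' @param ... overrides passed on to [cell_population_spec()].
#' @export
population_preset <- function(preset = c("P4", "P8", "P15"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    P4  = list(area_um2_mean = 80,  area_um2_sd = 20, circularity_target = 0.80),
    P8  = list(area_um2_mean = 330, area_um2_sd = 80, circularity_target = 0.65),
    P15 = list(area_um2_mean = 60,  area_um2_sd = 15, circularity_target = 0.30)
  )
  do.call(cell_population_spec, utils::modifyList(base, list(...)))
}

#' Relief-contrast rendering specification
#'
#' Oblique epi-illumination is emulated as an emboss: the rendered frame is
#' `background x vignette + relief_gain x (directional derivative of the
#' cell height map along the illumination azimuth) + noise`, clipped to
#' `[0, 255]`. This reproduces the bipolar bright-leading / dark-trailing
#' edge appearance that a luminance-based segmenter has to cope with.
#'
#' @param illumination_azimuth_deg direction of the shading, degrees
#'   (0 = along image x).
#' @param relief_gain contrast amplitude, luminance units per unit height
#'   slope (height is carried in um).
#' @param background_level mean background luminance in `[0, 255]`.
#' @param vignette_strength radial illumination falloff in `[0, 1)`;
#'   luminance at the frame corner is `(1 - strength)` of the centre.
#' @param noise_sd additive Gaussian noise, luminance units.
#' @return an object of class `relief_render_spec`.
#' @export
relief_render_spec <- function(illumination_azimuth_deg = 45,
                               relief_gain = 15,
                               background_level = 128,
                               vignette_strength = 0,
                               noise_sd = 3) {
  stopifnot(background_level >= 0, background_level <= 255,
            vignette_strength >= 0, vignette_strength < 1, noise_sd >= 0,
            relief_gain >= 0)
  structure(
    list(illumination_azimuth_deg = illumination_azimuth_deg,
         relief_gain = relief_gain, background_level = background_level,
         vignette_strength = vignette_strength, noise_sd = noise_sd),
    class = "relief_render_spec"
  )
}

# Sample ellipse geometry for one population draw (areas, axes, angles).
sample_cell_geometry <- function(pop) {
  n <- pop$n_cells
  if (n == 0L) {
    return(tibble::tibble(label = integer(), area_um2 = numeric(),
                          a_um = numeric(), b_um = numeric(), theta = numeric()))
  }
  if (pop$area_um2_sd > 0) {
    sdlog <- sqrt(log(1 + (pop$area_um2_sd / pop$area_um2_mean)^2))
    meanlog <- log(pop$area_um2_mean) - sdlog^2 / 2
    areas <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    areas <- rep(pop$area_um2_mean, n)
  }
  ax <- t(vapply(areas, ellipse_axes, numeric(2), circularity = pop$circularity_target))
  tibble::tibble(label = seq_len(n), area_um2 = areas,
                 a_um = ax[, 1], b_um = ax[, 2],
                 theta = stats::runif(n, 0, pi))
}

# Hard-core placement of cell centres inside the field, margins keeping
# every ellipse fully inside the frame. Errors out if the density is not
# placeable within bounded retries.
place_cells <- function(geom, width_um, height_um, min_gap_um, max_tries = 1000L) {
  n <- nrow(geom)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    margin <- geom$a_um[i] + 1
    if (2 * margin >= width_um || 2 * margin >= height_um) {
      stop("cell ", i, " (semi-major axis ", signif(geom$a_um[i], 3),
           " um) does not fit in the field", call. = FALSE)
    }
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, margin, width_um - margin)
      y <- stats::runif(1, margin, height_um - margin)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
        ok <- all(d2 >= (geom$a_um[i] + geom$a_um[j] + min_gap_um)^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) {
      stop("field capacity exceeded: only ", i - 1L, " of ", n,
           " cells could be placed with min_gap ", min_gap_um, " um",
           call. = FALSE)
    }
  }
  geom$cx_um <- cx; geom$cy_um <- cy
  geom
}

# Accumulate the smooth height map (um) and support mask of a set of
# elliptical cells; ellipsoidal-cap profile h0 * sqrt(1 - rho^2), whose
# steep shoulder puts the optical edge at the geometric support boundary.
render_height_map <- function(geom, nrow_px, ncol_px, psx, psy) {
  H <- matrix(0, nrow_px, ncol_px)
  M <- matrix(FALSE, nrow_px, ncol_px)
  xs <- (seq_len(ncol_px) - 0.5) * psx
  ys <- (seq_len(nrow_px) - 0.5) * psy
  for (i in seq_len(nrow(geom))) {
    a <- geom$a_um[i]; b <- geom$b_um[i]; th <- geom$theta[i]
    cx <- geom$cx_um[i]; cy <- geom$cy_um[i]
    j1 <- max(1L, floor((cx - a) / psx)); j2 <- min(ncol_px, ceiling((cx + a) / psx) + 1L)
    i1 <- max(1L, floor((cy - a) / psy)); i2 <- min(nrow_px, ceiling((cy + a) / psy) + 1L)
    dx <- xs[j1:j2] - cx; dy <- ys[i1:i2] - cy
    u <- outer(dy, dx, function(Y, X) X * cos(th) + Y * sin(th))
    v <- outer(dy, dx, function(Y, X) -X * sin(th) + Y * cos(th))
    rho2 <- (u / a)^2 + (v / b)^2
    inside <- rho2 <= 1
    h0 <- min(2 * b, 10)   # cell thickness scales with the minor axis, capped
    bump <- h0 * sqrt(pmax(1 - rho2, 0))
    H[i1:i2, j1:j2] <- H[i1:i2, j1:j2] + bump
    M[i1:i2, j1:j2] <- M[i1:i2, j1:j2] | inside
  }
  list(height = H, mask = M)
}

# Emboss-render a height map (um) into an 8-bit luminance matrix.
render_relief <- function(height, render, psx, psy) {
  nr <- nrow(height); nc <- ncol(height)
  az <- render$illumination_azimuth_deg * pi / 180
  g <- grad_xy(height, psx, psy)
  relief <- render$relief_gain * (cos(az) * g$gx + sin(az) * g$gy)
  bg <- render$background_level
  if (render$vignette_strength > 0) {
    xs <- (seq_len(nc) - (nc + 1) / 2); ys <- (seq_len(nr) - (nr + 1) / 2)
    r2 <- outer(ys^2, xs^2, "+")
    vig <- 1 - render$vignette_strength * r2 / max(r2)
    bg <- bg * vig
  }
  img <- bg + relief
  if (render$noise_sd > 0) img <- img + stats::rnorm(nr * nc, sd = render$noise_sd)
  clip255(img)
}

#' Simulate one relief-contrast field with exact ground truth
#'
#' Cells are smooth elliptical height bumps shaded by the directional
#' derivative along the illumination azimuth (bright leading edge, dark
#' trailing edge). Ground truth is computed from the analytic ellipses
#' before rasterization, so discretization error is part of what
#' downstream accuracy is measured against.
#'
#' @param pop a [cell_population_spec()].
#' @param render a [relief_render_spec()].
#' @param frame_size_px integer c(width, height) of the frame in pixels.
#' @param pixel_size_x_um,pixel_size_y_um physical pixel sizes.
#' @param time_h culture time stamped on the frame.
#' @param positions_um optional n x 2 matrix of cell centres (um). When
#'   supplied the hard-core placement is skipped, which allows fixtures
#'   with touching or overlapping cells; `n_cells` must match.
#' @return a list of class `synth_field` with elements
#'   `image` (a [calibrated_image()]), `truth` (a tibble with one row per
#'   cell: label, cx_um, cy_um, a_um, b_um, theta, area_um2, perimeter_um,
#'   circularity) and `mask` (logical matrix, union of cell supports).
#' @export
synth_field <- function(pop,
                        render = relief_render_spec(),
                        frame_size_px = c(512L, 512L),
                        pixel_size_x_um = 0.463,
                        pixel_size_y_um = pixel_size_x_um,
                        time_h = NA_real_,
                        positions_um = NULL) {
  stopifnot(inherits(pop, "cell_population_spec"),
            inherits(render, "relief_render_spec"),
            length(frame_size_px) == 2, all(frame_size_px >= 8))
  nc <- as.integer(frame_size_px[1]); nr <- as.integer(frame_size_px[2])
  with_seed(pop$seed, {
    geom <- sample_cell_geometry(pop)
    if (nrow(geom) > 0) {
      if (is.null(positions_um)) {
        geom <- place_cells(geom, width_um = nc * pixel_size_x_um,
                            height_um = nr * pixel_size_y_um,
                            min_gap_um = pop$min_gap_um)
      } else {
        stopifnot(nrow(positions_um) == nrow(geom), ncol(positions_um) == 2)
        geom$cx_um <- positions_um[, 1]
        geom$cy_um <- positions_um[, 2]
      }
      hm <- render_height_map(geom, nr, nc, pixel_size_x_um, pixel_size_y_um)
    } else {
      geom$cx_um <- numeric(0); geom$cy_um <- numeric(0)
      hm <- list(height = matrix(0, nr, nc), mask = matrix(FALSE, nr, nc))
    }
    px <- render_relief(hm$height, render, pixel_size_x_um, pixel_size_y_um)
    truth <- geom
    truth$perimeter_um <- ramanujan_perimeter(truth$a_um, truth$b_um)
    truth$area_um2 <- pi * truth$a_um * truth$b_um
    truth$circularity <- 4 * pi * truth$area_um2 / truth$perimeter_um^2
    truth <- truth[, c("label", "cx_um", "cy_um", "a_um", "b_um", "theta",
                       "area_um2", "perimeter_um", "circularity")]
    structure(
      list(image = calibrated_image(px, pixel_size_x_um, pixel_size_y_um,
                                    time_h = time_h),
           truth = tibble::as_tibble(truth),
           mask = hm$mask),
      class = "synth_field"
    )
  })
}

#' Growth-simulation specification
#'
#' Ground-truth exponential (optionally logistic-capped) growth of a
#' seeded well, sampled on an acquisition schedule. Defaults follow the
#' reference protocol: 3.0e4 cells seeded per 9.6 cm2 well, monitored
#' hourly from 24 h to 72 h.
#'
#' @param n0_cells_per_well initial cells per well at `schedule$start_h`.
#' @param doubling_time_h ground-truth doubling time, hours.
#' @param carrying_capacity optional logistic cap (cells per well).
#' @param schedule an [acquisition_schedule()] giving the sampling times.
#' @param layout a [plate_layout()]; its well area scales per-field counts.
#' @param count_noise `"poisson"` or `"none"`.
#' @param seed RNG seed.
#' @return an object of class `growth_sim_spec`.
#' @export
growth_sim_spec <- function(n0_cells_per_well = 3e4,
                            doubling_time_h = 20,
                            carrying_capacity = NULL,
                            schedule = acquisition_schedule(),
                            layout = plate_layout(),
                            count_noise = c("poisson", "none"),
                            seed = NULL) {
  stopifnot(n0_cells_per_well > 0, doubling_time_h > 0)
  if (!is.null(carrying_capacity)) stopifnot(carrying_capacity > 0)
  structure(
    list(n0_cells_per_well = n0_cells_per_well,
         doubling_time_h = doubling_time_h,
         carrying_capacity = carrying_capacity,
         schedule = schedule, layout = layout,
         count_noise = match.arg(count_noise), seed = seed),
    class = "growth_sim_spec"
  )
}

#' Expected per-well population of a growth simulation
#'
#' Exponential: `n(t) = n0 * 2^((t - start)/Td)`. With a carrying capacity
#' `K` the curve is the logistic solution with the same initial doubling
#' rate, `n(t) = K n0 / (n0 + (K - n0) 2^(-(t - start)/Td))`; `n0 = K` is a
#' fixed point.
#'
#' @param growth a [growth_sim_spec()].
#' @param time_h culture times, hours.
#' @return numeric vector of expected cells per well.
#' @export
expected_cells_per_well <- function(growth, time_h) {
  dt <- (time_h - growth$schedule$start_h) / growth$doubling_time_h
  n0 <- growth$n0_cells_per_well
  if (is.null(growth$carrying_capacity)) {
    n0 * 2^dt
  } else {
    K <- growth$carrying_capacity
    K * n0 / (n0 + (K - n0) * 2^(-dt))
  }
}

#' Simulate a time-lapse growth series of rendered fields
#'
#' The expected per-field count at time t is
#' `n(t) * field_area / well_area`, where the field area comes from the
#' frame size and pixel calibration. Realized counts are Poisson draws
#' when `count_noise = "poisson"`; each frame is rendered with
#' [synth_field()].
#'
#' @param growth a [growth_sim_spec()].
#' @param pop a [cell_population_spec()]; its `n_cells` and `seed` are
#'   overridden per frame.
#' @param render a [relief_render_spec()].
#' @param frame_size_px c(width, height) in pixels.
#' @param pixel_size_x_um,pixel_size_y_um pixel calibration of the frames.
#' @param render_frames if `FALSE`, skip rasterization and return counts
#'   only (fast path for count-level simulations).
#' @return a list of class `synth_timelapse`: `truth` (tibble with
#'   time_h, expected_count, n_cells) and `frames` (list of `synth_field`
#'   results, or `NULL` when `render_frames = FALSE`).
#' @export
synth_timelapse <- function(growth,
                            pop = cell_population_spec(),
                            render = relief_render_spec(),
                            frame_size_px = c(512L, 512L),
                            pixel_size_x_um = 0.463,
                            pixel_size_y_um = pixel_size_x_um,
                            render_frames = TRUE) {
  stopifnot(inherits(growth, "growth_sim_spec"))
  times <- unique(plan_schedule(growth$schedule)$time_h)
  field_mm2 <- prod(frame_size_px) * pixel_size_x_um * pixel_size_y_um / 1e6
  lambda <- expected_cells_per_well(growth, times) *
    field_mm2 / growth$layout$well_area_mm2
  with_seed(growth$seed, {
    n_cells <- if (growth$count_noise == "poisson") {
      stats::rpois(length(lambda), lambda)
    } else {
      as.integer(round(lambda))
    }
    frame_seeds <- sample.int(.Machine$integer.max - 1L, length(times))
    frames <- NULL
    if (render_frames) {
      frames <- lapply(seq_along(times), function(i) {
        pop_i <- pop
        pop_i$n_cells <- n_cells[i]
        pop_i$seed <- frame_seeds[i]
        synth_field(pop_i, render, frame_size_px,
                    pixel_size_x_um, pixel_size_y_um, time_h = times[i])
      })
    }
    structure(
      list(truth = tibble::tibble(time_h = times, expected_count = lambda,
                                  n_cells = n_cells),
           frames = frames),
      class = "synth_timelapse"
    )
  })
}

# ---- synthetic tube networks ------------------------------------------------

# Minimum angle (rad) between segments sharing a node, so rasterized
# junctions stay resolvable.
.MIN_BRANCH_ANGLE <- 40 * pi / 180

random_unit_vector <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

#' Simulate a capillary-like tube network with exact ground truth
#'
#' Grows a random embedded tree of straight tube segments, then rasterizes
#' each segment as a capsule (all voxels within `tube_radius_um` of the
#' centreline). Truth totals are computed from the generating polylines
#' before rasterization: total length is the sum of segment lengths and
#' branch points are nodes with three or more incident segments.
#'
#' @param n_segments number of straight segments to grow (>= 1).
#' @param segment_length_um_range c(min, max) segment length, um.
#' @param tube_radius_um tube radius, um.
#' @param dims_px integer vector of 2 (x, y) or 3 (x, y, z) voxel grid
#'   dimensions.
#' @param voxel_size_um per-axis voxel size, recycled to `length(dims_px)`.
#' @param branch_prob probability that a new segment starts at an interior
#'   node (creating a branch) rather than extending a leaf.
#' @param seed RNG seed.
#' @return a list of class `synth_network`: `mask` (binary matrix or 3-D
#'   array), `voxel_size_um`, and `truth` (list with `total_length_um`,
#'   `n_branch_points`, and a `segments` tibble of generating endpoints).
#' @export
synth_network <- function(n_segments = 10L,
                          segment_length_um_range = c(30, 80),
                          tube_radius_um = 5,
                          dims_px = c(256L, 256L),
                          voxel_size_um = 1,
                          branch_prob = 0.35,
                          seed = NULL) {
  stopifnot(n_segments >= 1, length(dims_px) %in% c(2L, 3L),
            tube_radius_um > 0, diff(segment_length_um_range) >= 0)
  d <- length(dims_px)
  vs <- rep_len(voxel_size_um, d)
  extent <- dims_px * vs
  if (any(extent < 2 * (max(segment_length_um_range) / 4 + tube_radius_um))) {
    stop("volume too small for the requested segments", call. = FALSE)
  }
  with_seed(seed, {
    margin <- tube_radius_um + 2 * max(vs)
    nodes <- matrix(extent / 2, nrow = 1)          # node coordinates, um
    node_dirs <- list(list())                      # unit dirs of incident segments
    segments <- list()
    tries_budget <- 400L * n_segments
    placed <- 0L
    while (placed < n_segments && tries_budget > 0L) {
      tries_budget <- tries_budget - 1L
      # choose attachment node: leaves extend, interior attachment branches
      deg <- vapply(node_dirs, length, integer(1))
      candidates <- which(deg < 4)
      if (placed == 0L) {
        at <- 1L
      } else if (stats::runif(1) < branch_prob) {
        at <- sample(rep(candidates, 2L), 1L)
      } else {
        leaves <- which(deg == 1)
        at <- if (length(leaves)) sample(rep(leaves, 2L), 1L) else sample(rep(candidates, 2L), 1L)
      }
      dir <- random_unit_vector(d)
      incident <- node_dirs[[at]]
      if (length(incident)) {
        angles_ok <- all(vapply(incident, function(u) {
          acos(pmin(pmax(sum(u * dir), -1), 1)) >= .MIN_BRANCH_ANGLE
        }, logical(1)))
        if (!angles_ok) next
      }
      len <- stats::runif(1, segment_length_um_range[1], segment_length_um_range[2])
      p0 <- nodes[at, ]
      p1 <- p0 + dir * len
      if (any(p1 < margin) || any(p1 > extent - margin)) next
      # keep the whole new segment clear of unrelated structure so the
      # rasterized tubes only meet at intended junctions
      if (length(segments)) {
        clear <- TRUE
        probes <- seq(0, 1, length.out = max(8L, ceiling(len / tube_radius_um)))
        for (s in segments) {
          shares_node <- all(s$from == p0) || all(s$to == p0)
          for (t_ in probes) {
            q <- p0 + dir * len * t_
            # near the shared node the tubes legitimately meet
            if (shares_node && sqrt(sum((q - p0)^2)) <= 2.5 * tube_radius_um + 2 * max(vs)) next
            dmin <- point_segment_distance(q, s$from, s$to)
            lim <- if (shares_node) 2 * tube_radius_um + 2 * max(vs)
                   else 2 * tube_radius_um + 4 * max(vs)
            if (dmin < lim) { clear <- FALSE; break }
          }
          if (!clear) break
        }
        if (!clear) next
      }
      nodes <- rbind(nodes, p1)
      node_dirs[[at]] <- c(node_dirs[[at]], list(dir))
      node_dirs[[length(node_dirs) + 1L]] <- list(-dir)
      segments[[length(segments) + 1L]] <- list(from = p0, to = p1, length_um = len)
      placed <- placed + 1L
    }
    if (placed < n_segments) {
      stop("could not embed ", n_segments, " segments (placed ", placed,
           ") within the volume", call. = FALSE)
    }
    deg <- vapply(node_dirs, length, integer(1))
    truth <- list(
      total_length_um = sum(vapply(segments, `[[`, numeric(1), "length_um")),
      n_branch_points = sum(deg >= 3),
      segments = tibble::tibble(
        from = lapply(segments, `[[`, "from"),
        to = lapply(segments, `[[`, "to"),
        length_um = vapply(segments, `[[`, numeric(1), "length_um")
      )
    )
    mask <- rasterize_capsules(segments, dims_px, vs, tube_radius_um)
    structure(list(mask = mask, voxel_size_um = vs, truth = truth),
              class = "synth_network")
  })
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# Rasterize capsule segments into a binary 2-D matrix or 3-D array.
# Voxel (i, j, k) has centre ((j - .5) vsx, (i - .5) vsy, (k - .5) vsz).
rasterize_capsules <- function(segments, dims_px, vs, radius_um) {
  d <- length(dims_px)
  nx <- dims_px[1]; ny <- dims_px[2]; nz <- if (d == 3) dims_px[3] else 1L
  vsx <- vs[1]; vsy <- vs[2]; vsz <- if (d == 3) vs[3] else 1
  arr <- array(0L, dim = c(ny, nx, nz))
  for (s in segments) {
    a <- s$from; b <- s$to
    if (d == 2) { a <- c(a, vsz / 2); b <- c(b, vsz / 2) }
    lo <- pmin(a, b) - radius_um; hi <- pmax(a, b) + radius_um
    j1 <- max(1L, floor(lo[1] / vsx)); j2 <- min(nx, ceiling(hi[1] / vsx) + 1L)
    i1 <- max(1L, floor(lo[2] / vsy)); i2 <- min(ny, ceiling(hi[2] / vsy) + 1L)
    k1 <- max(1L, floor(lo[3] / vsz)); k2 <- min(nz, ceiling(hi[3] / vsz) + 1L)
    xs <- (j1:j2 - 0.5) * vsx; ys <- (i1:i2 - 0.5) * vsy; zs <- (k1:k2 - 0.5) * vsz
    ab <- b - a; ab2 <- sum(ab^2)
    # distance of every voxel centre in the bbox to segment ab
    g <- expand.grid(y = ys, x = xs, z = zs)
    px <- cbind(g$x, g$y, g$z)
    t <- ((px[, 1] - a[1]) * ab[1] + (px[, 2] - a[2]) * ab[2] +
            (px[, 3] - a[3]) * ab[3]) / ab2
    t <- pmin(pmax(t, 0), 1)
    dx <- px[, 1] - (a[1] + t * ab[1])
    dy <- px[, 2] - (a[2] + t * ab[2])
    dz <- px[, 3] - (a[3] + t * ab[3])
    inside <- (dx^2 + dy^2 + dz^2) <= radius_um^2
    sub <- array(arr[i1:i2, j1:j2, k1:k2], dim = c(length(ys), length(xs), length(zs)))
    sub[inside] <- 1L
    arr[i1:i2, j1:j2, k1:k2] <- sub
  }
  if (d == 2) arr <- matrix(arr, ny, nx)
  arr
}

# ---- microwell grids and spheroid series ------------------------------------

#' Simulate a microwell-array chip image
#'
#' Renders a grid of round microwells (darkened discs with an embossed
#' rim) on a uniform background, with exact centre ground truth. Default
#' geometry: 500 um well diameter at 600 um pitch.
#'
#' @param n_rows,n_cols microwell grid dimensions.
#' @param pitch_um centre-to-centre spacing, um.
#' @param well_diameter_um microwell diameter, um.
#' @param pixel_size_um pixel calibration of the rendered image.
#' @param offset_px integer c(dx, dy) translation of the whole grid, px.
#' @param depth_contrast luminance drop inside a well.
#' @param noise_sd additive Gaussian noise, luminance units.
#' @param seed RNG seed.
#' @return list of class `synth_grid`: `image` (a [calibrated_image()])
#'   and `truth` (tibble of centre coordinates cx_px, cy_px, cx_um, cy_um).
#' @export
synth_microwell_grid <- function(n_rows = 3L, n_cols = 3L,
                                 pitch_um = 600, well_diameter_um = 500,
                                 pixel_size_um = 3,
                                 offset_px = c(0L, 0L),
                                 depth_contrast = 40,
                                 noise_sd = 3,
                                 seed = NULL) {
  ps <- pixel_size_um
  pitch_px <- pitch_um / ps
  r_px <- well_diameter_um / 2 / ps
  nc <- as.integer(ceiling((n_cols + 0.6) * pitch_px))
  nr <- as.integer(ceiling((n_rows + 0.6) * pitch_px))
  cx <- (seq_len(n_cols) - 0.5 + 0.3) * pitch_px + offset_px[1]
  cy <- (seq_len(n_rows) - 0.5 + 0.3) * pitch_px + offset_px[2]
  centers <- expand.grid(cx_px = cx, cy_px = cy)
  with_seed(seed, {
    img <- matrix(160, nr, nc)
    xs <- seq_len(nc) - 0.5; ys <- seq_len(nr) - 0.5
    for (i in seq_len(nrow(centers))) {
      dx2 <- (xs - centers$cx_px[i])^2
      dy2 <- (ys - centers$cy_px[i])^2
      r <- sqrt(outer(dy2, dx2, "+"))
      # bowl-shaped darkening with a bright rim highlight
      inside <- r <= r_px
      img[inside] <- img[inside] - depth_contrast * (1 - (r[inside] / r_px)^2)
      rim <- r > r_px & r <= r_px + 2
      img[rim] <- img[rim] + 15
    }
    if (noise_sd > 0) img <- img + stats::rnorm(nr * nc, sd = noise_sd)
    truth <- tibble::as_tibble(centers)
    truth$cx_um <- truth$cx_px * ps
    truth$cy_um <- truth$cy_px * ps
    structure(list(image = calibrated_image(clip255(img), ps, ps),
                   truth = truth),
              class = "synth_grid")
  })
}

#' Simulate a per-microwell aggregate-formation image series
#'
#' Emulates the three qualitative regimes of spheroid formation in a
#' single microwell: `"compacting"` (loose aggregate that condenses into
#' one smooth, high-circularity spheroid), `"dissociating"` (loose
#' aggregate that breaks up into scattered single cells), and `"none"`
#' (cells stay scattered). Truth per frame (projected area, circularity of
#' the largest fragment, fragment count) is measured on the generator's
#' own noise-free support mask.
#'
#' @param mode `"compacting"`, `"dissociating"`, or `"none"`.
#' @param n_frames number of frames (>= 2).
#' @param n_cells number of seeded cells in the well.
#' @param well_diameter_um,pitch_um microwell geometry; the rendered ROI is
#'   a square of side `pitch_um`.
#' @param spheroid_diameter_um final compacted-spheroid diameter.
#' @param cell_radius_um radius of one seeded cell.
#' @param pixel_size_um pixel calibration.
#' @param t_start_h,t_step_h time stamps of the frames.
#' @param render a [relief_render_spec()].
#' @param seed RNG seed.
#' @return list of class `synth_spheroid_series`: `frames` (list of
#'   [calibrated_image()]), `truth` (tibble time_h, area_um2, circularity,
#'   n_fragments) and `masks` (list of logical matrices).
#' @export
synth_spheroid_series <- function(mode = c("compacting", "dissociating", "none"),
                                  n_frames = 9L,
                                  n_cells = 12L,
                                  well_diameter_um = 500,
                                  pitch_um = 600,
                                  spheroid_diameter_um = 200,
                                  cell_radius_um = 30,
                                  pixel_size_um = 2,
                                  t_start_h = 2, t_step_h = 3,
                                  render = relief_render_spec(),
                                  seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 2, n_cells >= 2)
  ps <- pixel_size_um
  npx <- as.integer(round(pitch_um / ps))
  ctr <- pitch_um / 2
  with_seed(seed, {
    # initial positions: scattered through the well mouth, non-overlapping
    r_spread <- well_diameter_um / 2 - cell_radius_um - 5
    ang <- stats::runif(n_cells, 0, 2 * pi)
    rad <- r_spread * sqrt(stats::runif(n_cells, 0.15, 1))
    p0 <- cbind(ctr + rad * cos(ang), ctr + rad * sin(ang))
    p0 <- spread_points(p0, min_dist = 2 * cell_radius_um + 18,
                        lo = cell_radius_um + 2, hi = pitch_um - cell_radius_um - 2)
    # tight cluster positions: packed around the centre
    tight <- cluster_positions(n_cells, ctr, cell_radius_um,
                               max_r = spheroid_diameter_um / 2 - cell_radius_um)
    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    times <- t_start_h + (seq_len(n_frames) - 1L) * t_step_h
    phase <- (seq_len(n_frames) - 1L) / (n_frames - 1L)   # 0 -> 1
    for (f in seq_len(n_frames)) {
      s <- phase[f]
      if (mode == "none") {
        pos <- p0
        shapes <- cells_as_discs(pos, cell_radius_um)
      } else if (mode == "dissociating") {
        # loosely gathered aggregate at first, then cells move apart
        if (s <= 1 / 4) {
          pos <- tight + (p0 - tight) * 0.2
        } else {
          w <- (s - 1 / 4) / (3 / 4)
          out <- tight + (p0 - tight) * (0.2 + 1.2 * w)
          out[, 1] <- pmin(pmax(out[, 1], cell_radius_um + 2), pitch_um - cell_radius_um - 2)
          out[, 2] <- pmin(pmax(out[, 2], cell_radius_um + 2), pitch_um - cell_radius_um - 2)
          pos <- out
        }
        shapes <- cells_as_discs(pos, cell_radius_um)
      } else { # compacting
        if (s < 0.5) {
          w <- s / 0.5
          pos <- (1 - w) * p0 + w * tight
          shapes <- cells_as_discs(pos, cell_radius_um)
        } else {
          # compacted spheroid, radius easing down to its final value; the
          # dome carries cellular surface texture (constituent cells), which
          # is what makes a real spheroid optically dense rather than flat
          w <- (s - 0.5) / 0.5
          r_start <- spheroid_diameter_um / 2 + cell_radius_um
          r_now <- r_start - w * (r_start - spheroid_diameter_um / 2)
          bump_r <- 10
          tex <- disc_fill_positions(ctr, max_r = max(r_now - bump_r, bump_r),
                                     spacing = 2.3 * bump_r)
          shapes <- rbind(
            tibble::tibble(cx_um = ctr, cy_um = ctr,
                           a_um = r_now, b_um = r_now, theta = 0),
            tibble::tibble(cx_um = tex[, 1], cy_um = tex[, 2],
                           a_um = bump_r, b_um = bump_r, theta = 0)
          )
        }
      }
      hm <- render_height_map(shapes, npx, npx, ps, ps)
      px <- render_relief(hm$height, render, ps, ps)
      frames[[f]] <- calibrated_image(px, ps, ps, time_h = times[f])
      masks[[f]] <- hm$mask
      truth[[f]] <- mask_shape_stats(hm$mask, ps, ps)
    }
    truth <- dplyr::bind_rows(truth)
    truth$time_h <- times
    structure(
      list(frames = frames,
           truth = truth[, c("time_h", "area_um2", "circularity", "n_fragments")],
           masks = masks, mode = mode),
      class = "synth_spheroid_series"
    )
  })
}

# Each cell body is a disc carrying three interior sub-bumps (nucleus and
# organelle scale), so cell interiors are optically textured rather than
# flat; the support mask is still the disc.
cells_as_discs <- function(pos, r) {
  n <- nrow(pos)
  base <- tibble::tibble(cx_um = pos[, 1], cy_um = pos[, 2],
                         a_um = r, b_um = r, theta = 0)
  ang <- rep(c(0, 2 * pi / 3, 4 * pi / 3), n) + rep(seq_len(n) * 0.7, each = 3)
  off <- 0.45 * r
  tex <- tibble::tibble(
    cx_um = rep(pos[, 1], each = 3) + off * cos(ang),
    cy_um = rep(pos[, 2], each = 3) + off * sin(ang),
    a_um = 0.38 * r, b_um = 0.38 * r, theta = 0
  )
  rbind(base, tex)
}

# Push points apart until pairwise distances exceed min_dist (bounded).
spread_points <- function(p, min_dist, lo, hi, iters = 200L) {
  n <- nrow(p)
  for (it in seq_len(iters)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      d <- sqrt(rowSums((p - matrix(p[i, ], n, 2, byrow = TRUE))^2))
      d[i] <- Inf
      j <- which.min(d)
      if (d[j] < min_dist) {
        dir <- p[i, ] - p[j, ]
        nd <- sqrt(sum(dir^2))
        dir <- if (nd < 1e-9) random_unit_vector(2) else dir / nd
        p[i, ] <- pmin(pmax(p[i, ] + dir * (min_dist - d[j]) * 0.6, lo), hi)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  p
}

# Complete concentric rings of points covering a disc, for surface texture.
disc_fill_positions <- function(ctr, max_r, spacing) {
  pts <- matrix(ctr, 1, 2)
  radii <- seq(spacing, max_r, by = spacing)
  # always texture the outermost annulus so the support edge is covered
  if (!length(radii) || max_r - radii[length(radii)] > spacing / 2) {
    radii <- c(radii, max_r)
  }
  for (rr in radii) {
    m <- max(6L, ceiling(2 * pi * rr / spacing))
    a <- seq(0, 2 * pi, length.out = m + 1L)[seq_len(m)] + rr
    pts <- rbind(pts, cbind(ctr + rr * cos(a), ctr + rr * sin(a)))
  }
  pts
}

# Deterministic tight packing: concentric rings around the centre.
cluster_positions <- function(n, ctr, cell_r, max_r) {
  pos <- matrix(ctr, 1, 2)
  ring <- 1L
  while (nrow(pos) < n) {
    r <- min(ring * 1.55 * cell_r, max_r)
    k <- max(6L * ring, n - nrow(pos))
    a <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)] + 0.3 * ring
    pos <- rbind(pos, cbind(ctr + r * cos(a), ctr + r * sin(a)))
    ring <- ring + 1L
  }
  pos[seq_len(n), , drop = FALSE]
}

# Area / circularity of largest fragment / fragment count of a binary mask.
mask_shape_stats <- function(mask, psx, psy) {
  lab <- label_components(mask)
  n_frag <- max(lab)
  if (n_frag == 0L) {
    return(tibble::tibble(area_um2 = 0, circularity = NA_real_, n_fragments = 0L))
  }
  counts <- tabulate(lab[lab > 0], nbins = n_frag)
  big <- which.max(counts)
  per <- crofton_perimeter(lab == big, psx, psy)
  area_big <- counts[big] * psx * psy
  tibble::tibble(
    area_um2 = sum(counts) * psx * psy,
    circularity = min(4 * pi * area_big / per^2, 1),
    n_fragments = n_frag
  )
}
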