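#' Segmentation parameters
#'
#' Tunable parameters of the relief-contrast segmentation pipeline
#' (illumination flattening, gradient-energy texture map, thresholding,
#' object filtering, and watershed splitting of touching cells).
#'
#' @param background_scale_um spatial scale of the illumination flattening;
#'   must be well above a cell diameter.
#' @param texture_scale_um smoothing scale of the gradient-energy map;
#'   roughly the width of the relief edge band.
#' @param threshold_method `"robust"` (energy noise floor at
#'   `median + robust_k * MAD`, well suited to maps whose foreground tail
#'   is heavy), `"otsu"`, or `"fixed"`.
#' @param robust_k multiple of the MAD above the median for the robust
#'   threshold.
#' @param fixed_threshold threshold on the energy map when
#'   `threshold_method = "fixed"`.
#' @param refine_fraction per-object boundary refinement: after the global
#'   threshold, each object is re-thresholded at this fraction of its own
#'   99th-percentile energy on a fine-scale energy map and replaced by the
#'   convex hull of the result, which removes the smoothing halo around
#'   each cell. `NULL` disables refinement.
#' @param refine_scale_um scale of the fine energy map used for boundary
#'   refinement.
#' @param min_cell_area_um2 objects smaller than this are discarded.
#' @param split_touching split merged objects by a distance-transform
#'   watershed.
#' @param h_maxima_depth minimum watershed seed suppression depth, px of
#'   the distance transform; per component the effective depth is
#'   `max(h_maxima_depth, 0.25 * max(distance))`, since the medial ridge of
#'   a large object wobbles with its boundary rasterization.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_scale_um = 100,
                                texture_scale_um = 1,
                                threshold_method = c("robust", "otsu", "fixed"),
                                robust_k = 4,
                                fixed_threshold = NULL,
                                refine_fraction = 0.6,
                                refine_scale_um = 0.4,
                                min_cell_area_um2 = 30,
                                split_touching = TRUE,
                                h_maxima_depth = 3) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(background_scale_um > 0, texture_scale_um > 0,
            min_cell_area_um2 >= 0, h_maxima_depth > 0, robust_k > 0)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold must be supplied when threshold_method = 'fixed'",
         call. = FALSE)
  }
  if (!is.null(refine_fraction)) {
    stopifnot(refine_fraction > 0, refine_fraction < 1, refine_scale_um > 0)
  }
  structure(
    list(background_scale_um = background_scale_um,
         texture_scale_um = texture_scale_um,
         threshold_method = threshold_method,
         robust_k = robust_k,
         fixed_threshold = fixed_threshold,
         refine_fraction = refine_fraction,
         refine_scale_um = refine_scale_um,
         min_cell_area_um2 = min_cell_area_um2,
         split_touching = isTRUE(split_touching),
         h_maxima_depth = h_maxima_depth),
    class = "segmentation_params"
  )
}

#' Flatten slowly varying illumination
#'
#' Estimates the illumination background as a quadratic surface fitted to
#' block medians on a grid of scale `background_scale_um` and subtracts it,
#' preserving the global mean luminance. Block medians are insensitive to
#' the bipolar (zero-mean) relief edges of the cells, and a quadratic
#' surface captures linear ramps and radial vignetting exactly.
#'
#' @param img a [calibrated_image()].
#' @param background_scale_um grid scale of the background estimate; must
#'   map to at least 2 px.
#' @return a [calibrated_image()] with flattened background.
#' @export
flatten_background <- function(img, background_scale_um = 100) {
  stopifnot(inherits(img, "cellmon_image"))
  px <- img$pixels
  s_px <- round(background_scale_um / min(img$pixel_size_x_um, img$pixel_size_y_um))
  if (s_px < 2) {
    stop("background_scale_um maps to fewer than 2 px at this calibration",
         call. = FALSE)
  }
  fit <- fit_background_surface(px, s_px)
  out <- px - (fit - mean(fit))
  img$pixels <- clip255(out)
  img
}

# Quadratic surface fitted by least squares to block medians.
fit_background_surface <- function(px, block_px) {
  nr <- nrow(px); nc <- ncol(px)
  block_px <- min(block_px, nr, nc)
  ri <- split(seq_len(nr), ceiling(seq_len(nr) / block_px))
  ci <- split(seq_len(nc), ceiling(seq_len(nc) / block_px))
  med <- matrix(NA_real_, length(ri), length(ci))
  yc <- vapply(ri, function(i) mean(i), numeric(1))
  xc <- vapply(ci, function(j) mean(j), numeric(1))
  for (i in seq_along(ri)) {
    for (j in seq_along(ci)) {
      med[i, j] <- stats::median(px[ri[[i]], ci[[j]]])
    }
  }
  df <- data.frame(z = as.vector(med),
                   x = rep(xc, each = length(yc)),
                   y = rep(yc, times = length(xc)))
  # centre/scale coordinates for numerical stability
  df$x <- (df$x - nc / 2) / nc
  df$y <- (df$y - nr / 2) / nr
  # drop to a linear (or constant) surface when the block grid is too
  # coarse to identify the quadratic terms
  nb <- nrow(df)
  fit <- if (nb >= 9) {
    stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = df)
  } else if (nb >= 4) {
    stats::lm(z ~ x + y, data = df)
  } else {
    NULL
  }
  X <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - nc / 2) / nc
  Y <- (matrix(seq_len(nr), nr, nc) - nr / 2) / nr
  if (is.null(fit)) return(matrix(stats::median(df$z), nr, nc))
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  if (length(b) == 3L) {
    b[1] + b[2] * X + b[3] * Y
  } else {
    b[1] + b[2] * X + b[3] * Y + b[4] * X^2 + b[5] * Y^2 + b[6] * X * Y
  }
}

#' Gradient-energy texture map
#'
#' Converts the bipolar relief edges into a unipolar cell-presence signal:
#' derivative-of-Gaussian gradient magnitude plus a luminance-amplitude
#' term, smoothed at `texture_scale_um`. Zero on constant regions, high on
#' cell bodies and edges; equivariant under 90-degree rotations.
#'
#' @param img a [calibrated_image()] (ideally after
#'   [flatten_background()]).
#' @param texture_scale_um Gaussian smoothing scale, um.
#' @return a `cellmon_map`: numeric matrix with calibration attributes.
#' @export
texture_energy <- function(img, texture_scale_um = 2) {
  stopifnot(inherits(img, "cellmon_image"), texture_scale_um > 0)
  sigma_px <- texture_scale_um / min(img$pixel_size_x_um, img$pixel_size_y_um)
  # derivative-of-Gaussian gradient magnitude (denoise, gradient, smooth)
  # plus a luminance-amplitude term: the bipolar relief shading crosses
  # zero inside a cell, where the gradient term takes over, while the
  # amplitude term covers the bright/dark lobes; together they give a
  # gap-free unipolar cell-presence signal. px-spacing gradient keeps
  # 90-degree symmetry.
  if (diff(range(img$pixels)) < 1e-12) {
    e <- matrix(0, nrow(img$pixels), ncol(img$pixels))
  } else {
    sm <- gaussian_smooth(img$pixels, sigma_px)
    g <- grad_xy(sm)
    e <- sqrt(g$gx^2 + g$gy^2)
    amp <- abs(sm - stats::median(sm))
    e <- gaussian_smooth(e + 0.5 * amp, sigma_px)
  }
  structure(e, class = c("cellmon_map", "matrix"),
            pixel_size_x_um = img$pixel_size_x_um,
            pixel_size_y_um = img$pixel_size_y_um)
}

#' Binarize an energy map into a foreground mask
#'
#' Thresholds the texture-energy map (robust noise floor by default, Otsu
#' or a fixed value on request), then applies morphological closing, fills
#' holes, removes objects smaller than `min_cell_area_um2`, and optionally
#' refines each object's boundary. A degenerate (constant) map yields an
#' empty mask with attribute `degenerate = TRUE` rather than an error.
#'
#' @param map a `cellmon_map` from [texture_energy()].
#' @param params a [segmentation_params()].
#' @return a `cellmon_mask`: integer 0/1 matrix with calibration
#'   attributes and a `degenerate` flag.
#' @export
binarize <- function(map, params = segmentation_params(), refine_map = NULL) {
  stopifnot(inherits(map, "cellmon_map"), inherits(params, "segmentation_params"))
  psx <- attr(map, "pixel_size_x_um"); psy <- attr(map, "pixel_size_y_um")
  m <- unclass(map); attributes(m) <- list(dim = dim(map))
  rng <- range(m)
  new_mask <- function(bin, degenerate = FALSE) {
    structure(bin, class = c("cellmon_mask", "matrix"),
              pixel_size_x_um = psx, pixel_size_y_um = psy,
              degenerate = degenerate)
  }
  if (diff(rng) < 1e-9) {
    return(new_mask(matrix(0L, nrow(m), ncol(m)), degenerate = TRUE))
  }
  noise_floor <- stats::median(m) + params$robust_k * stats::mad(m)
  thr <- switch(params$threshold_method,
    fixed = params$fixed_threshold,
    robust = noise_floor,
    otsu = {
      norm <- (m - rng[1]) / diff(rng)
      ot <- rng[1] + EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng)
      # on a frame with no real foreground Otsu splits the noise; never
      # threshold below the noise floor of the energy map (a zero MAD
      # means a noiseless plateau, where the floor is meaningless)
      if (stats::mad(m) > 0) max(ot, noise_floor) else ot
    }
  )
  bin <- (m > thr) * 1
  close_r <- max(2L, round(1.5 * params$texture_scale_um / min(psx, psy)))
  brush <- EBImage::makeBrush(2L * close_r + 1L, shape = "disc")
  bin <- EBImage::closing(EBImage::Image(bin), brush)
  bin <- EBImage::fillHull(bin)
  bin <- EBImage::imageData(bin)
  min_px <- params$min_cell_area_um2 / (psx * psy)
  drop_small <- function(bin) {
    if (min_px > 0 && any(bin > 0)) {
      lab <- label_components(bin)
      counts <- tabulate(lab[lab > 0L])
      drop <- which(counts < min_px)
      if (length(drop)) bin[lab %in% drop] <- 0
    }
    bin
  }
  bin <- drop_small(bin)
  if (!is.null(params$refine_fraction) && any(bin > 0)) {
    rm_ <- if (is.null(refine_map)) m else unclass(refine_map)
    bin <- refine_objects(bin, rm_, params$refine_fraction)
    bin <- drop_small(bin)
  }
  new_mask(matrix(as.integer(bin > 0), nrow(m), ncol(m)))
}

#' Detect, label and count cells in a relief-contrast frame
#'
#' Full pipeline: [flatten_background()] -> [texture_energy()] ->
#' [binarize()] -> connected components, with an optional
#' distance-transform watershed split of touching cells (seed suppression
#' depth `h_maxima_depth`). Objects touching the frame border are counted
#' but flagged `border = TRUE` so morphometrics can exclude them.
#'
#' @param img a [calibrated_image()].
#' @param params a [segmentation_params()].
#' @return an object of class `cell_labels`: list with `label_image`
#'   (integer matrix, 0 = background, 1..n = cells), `n_cells`, `cells`
#'   (tibble: label, cx_px, cy_px, area_px, border), `mask`
#'   (the `cellmon_mask`), and the pixel calibration.
#' @export
detect_cells <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "cellmon_image"))
  flat <- flatten_background(img, params$background_scale_um)
  emap <- texture_energy(flat, params$texture_scale_um)
  fine <- if (!is.null(params$refine_fraction) &&
              params$refine_scale_um < params$texture_scale_um) {
    texture_energy(flat, params$refine_scale_um)
  } else NULL
  params_coarse <- params
  params_coarse$refine_fraction <- NULL
  mask <- binarize(emap, params_coarse)
  lab <- label_components(mask)
  min_px <- params$min_cell_area_um2 / (img$pixel_size_x_um * img$pixel_size_y_um)
  if (params$split_touching && max(lab) > 0) {
    lab <- split_components(lab, params$h_maxima_depth)
    # drop split fragments that fell below the size cutoff
    counts <- tabulate(lab[lab > 0L])
    small <- which(counts < min_px)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  if (!is.null(params$refine_fraction) && max(lab) > 0) {
    rmap <- if (is.null(fine)) unclass(emap) else unclass(fine)
    lab <- refine_labels(lab, rmap, params$refine_fraction)
    counts <- tabulate(lab[lab > 0L])
    small <- which(counts < min_px)
    if (length(small)) lab[lab %in% small] <- 0L
    refined <- mask
    refined[] <- as.integer(lab > 0L)
    mask <- refined
  }
  lab <- relabel_consecutive(lab)
  n <- max(lab)
  cells <- label_stats(lab)
  structure(
    list(label_image = lab, n_cells = n, cells = cells, mask = mask,
         pixel_size_x_um = img$pixel_size_x_um,
         pixel_size_y_um = img$pixel_size_y_um),
    class = "cell_labels"
  )
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  out <- lab
  out[lab > 0L] <- lut[lab[lab > 0L]]
  out
}

label_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(label = integer(), cx_px = numeric(),
                          cy_px = numeric(), area_px = integer(),
                          border = logical()))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, nbins = n)
  cx <- as.numeric(tapply(cols, l, mean)) - 0.5
  cy <- as.numeric(tapply(rows, l, mean)) - 0.5
  on_border <- rows == 1L | rows == nrow(lab) | cols == 1L | cols == ncol(lab)
  border <- as.logical(tapply(on_border, l, any))
  tibble::tibble(label = seq_len(n), cx_px = cx, cy_px = cy,
                 area_px = area, border = border)
}

#' @export
print.cell_labels <- function(x, ...) {
  cat(sprintf("<cell_labels> %d cells in %d x %d px frame\n",
              x$n_cells, ncol(x$label_image), nrow(x$label_image)))
  invisible(x)
}

#' Confluency of a foreground mask
#'
#' Fraction of the field covered by cells: foreground pixels over total
#' pixels. Always in `[0, 1]` and invariant under rotation/mirroring.
#'
#' @param mask a `cellmon_mask` (from [binarize()]) or any 0/1 matrix.
#' @return scalar fraction in `[0, 1]`.
#' @export
confluency <- function(mask) {
  m <- unclass(mask)
  stopifnot(all(m %in% c(0, 1)))
  mean(m)
}

# Per-object boundary refinement: re-threshold each object at a fraction
# of its own upper-quantile energy (half-max style) and take the convex
# hull of the result. Removes the smoothing halo that a single global
# threshold leaves around every cell.
refine_objects <- function(bin, emap, fraction) {
  (refine_labels(label_components(bin), emap, fraction) > 0L) * 1L
}

# Same refinement, keeping label identities (each refined cell is clipped
# to its own label region, so watershed-split neighbours stay apart).
refine_labels <- function(lab, emap, fraction) {
  n <- max(lab)
  if (n == 0L) return(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  bb <- label_bboxes(lab)
  for (k in seq_len(n)) {
    if (is.null(bb[[k]])) next
    r <- bb[[k]]$rows[1]:bb[[k]]$rows[2]; c <- bb[[k]]$cols[1]:bb[[k]]$cols[2]
    obj <- lab[r, c, drop = FALSE] == k
    sub <- emap[r, c, drop = FALSE]
    thr <- fraction * stats::quantile(sub[obj], 0.99, names = FALSE)
    m2 <- (sub > thr & obj) * 1
    if (!any(m2 > 0)) { m2 <- obj * 1 } else {
      # the refined set splits where the bipolar shading crosses zero
      # inside the cell; the convex hull restores the interior (cell
      # bodies are near-convex), clipped to the parent object so
      # neighbours stay apart
      # drop stray above-threshold pixels so they cannot stretch the hull
      m2o <- EBImage::imageData(EBImage::opening(EBImage::Image(m2),
                                                 EBImage::makeBrush(3L, "disc")))
      if (any(m2o > 0)) m2 <- m2o
      m2 <- convex_hull_mask(m2) * obj
      if (!any(m2 > 0)) m2 <- obj * 1
    }
    sel <- m2 > 0
    block <- out[r, c]
    block[sel] <- k
    out[r, c] <- block
  }
  out
}

# Filled convex hull of the foreground of a small binary matrix.
convex_hull_mask <- function(m) {
  pts <- which(m > 0, arr.ind = TRUE)
  if (nrow(pts) < 3L) return((m > 0) * 1L)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  out <- matrix(0L, nrow(m), ncol(m))
  np <- nrow(hp)
  for (i in seq_len(np)) {
    a <- hp[i, ]
    b <- hp[if (i == np) 1L else i + 1L, ]
    nsteps <- max(abs(a - b)) + 1L
    rr <- round(seq(a[1], b[1], length.out = nsteps))
    cc <- round(seq(a[2], b[2], length.out = nsteps))
    out[cbind(rr, cc)] <- 1L
  }
  EBImage::imageData(EBImage::fillHull(EBImage::Image(out)))
}


# Distance-transform watershed applied per connected component, with a
# seed-suppression depth that scales with the component's own thickness:
# boundary rasterization makes the medial ridge of a large object wobble
# by a few pixels, so an absolute depth alone over-splits large cells.
split_components <- function(lab, h_min) {
  n <- max(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  bb <- label_bboxes(lab)
  for (k in seq_len(n)) {
    if (is.null(bb[[k]])) next
    r <- bb[[k]]$rows[1]:bb[[k]]$rows[2]; c <- bb[[k]]$cols[1]:bb[[k]]$cols[2]
    obj <- (lab[r, c, drop = FALSE] == k) * 1
    # de-wiggle the contour before the distance transform so the medial
    # ridge of an elongated object stays monotone; a genuine neck between
    # touching cells is much deeper than the rasterization wobble
    objs <- (gaussian_smooth(obj, 2) > 0.5) * 1
    if (!any(objs > 0)) objs <- obj
    dm <- EBImage::distmap(EBImage::Image(objs))
    tol <- max(h_min, 0.25 * max(dm))
    ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tol, ext = 1))
    storage.mode(ws) <- "integer"
    # reassign pixels shaved off by the contour smoothing to the nearest
    # watershed region (deterministic label order)
    box <- EBImage::makeBrush(3L, "box")
    for (it in 1:4) {
      miss <- obj > 0 & ws == 0L
      if (!any(miss)) break
      for (l in seq_len(max(ws))) {
        dl <- EBImage::imageData(EBImage::dilate(EBImage::Image((ws == l) * 1), box))
        ws[miss & dl > 0] <- l
        miss <- obj > 0 & ws == 0L
      }
    }
    m <- max(ws)
    sel <- ws > 0L
    block <- out[r, c]
    block[sel] <- ws[sel] + nxt
    out[r, c] <- block
    nxt <- nxt + m
  }
  out
}
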