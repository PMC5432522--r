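# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Odd-width 1-D Gaussian kernel (sd in pixels), normalised to sum 1.
gaussian_kernel <- function(sigma_px, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_px))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a matrix with edge replication, via the
# EBImage FFT convolution on a padded copy (padding removes wrap-around).
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k1 <- gaussian_kernel(sigma_px, r)
  k2 <- outer(k1, k1)
  # replicate-pad so the kernel never exceeds the (possibly tiny) input
  pr <- max(0L, as.integer(ceiling((2L * r + 2L - min(dim(m))) / 2)))
  if (pr > 0L) {
    ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
    ci <- c(rep(1L, pr), seq_len(ncol(m)), rep(ncol(m), pr))
    mp <- m[ri, ci, drop = FALSE]
    sm <- EBImage::imageData(EBImage::filter2(EBImage::Image(mp), k2, boundary = "replicate"))
    sm[pr + seq_len(nrow(m)), pr + seq_len(ncol(m)), drop = FALSE]
  } else {
    EBImage::imageData(EBImage::filter2(EBImage::Image(m), k2, boundary = "replicate"))
  }
}

# Central-difference gradient of a matrix with replicated borders.
# Returns list(gx, gy): gx along columns (image x), gy along rows (image y),
# per pixel-size unit supplied.
grad_xy <- function(m, psx = 1, psy = 1) {
  nr <- nrow(m); nc <- ncol(m)
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  list(gx = (right - left) / (2 * psx), gy = (down - up) / (2 * psy))
}

# Ramanujan's closed-form approximation to the perimeter of an ellipse with
# semi-axes a, b (exact for a == b).
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Semi-axes (a >= b) of the ellipse with the given area whose
# Ramanujan-perimeter circularity 4*pi*A/P^2 equals `circularity`.
ellipse_axes <- function(area_um2, circularity) {
  stopifnot(area_um2 > 0, circularity > 0, circularity <= 1)
  circ_of <- function(q) {
    a <- sqrt(area_um2 / (pi * q))
    p <- ramanujan_perimeter(a, a * q)
    4 * pi * area_um2 / p^2
  }
  q <- if (circularity >= 1 - 1e-12) 1 else {
    stats::uniroot(function(q) circ_of(q) - circularity,
                   interval = c(1e-5, 1), tol = 1e-12)$root
  }
  a <- sqrt(area_um2 / (pi * q))
  c(a = a, b = a * q)
}

# Clip numeric values into [0, 255].
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Binary connected-component labelling (8-connectivity) returning an
# integer matrix, thin wrapper so callers don't touch EBImage types.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  storage.mode(lab) <- "integer"
  EBImage::imageData(lab)
}

# Bounding boxes of all labels in one pass: list indexed by label id with
# elements rows = c(r1, r2), cols = c(c1, c2); NULL for absent labels.
label_bboxes <- function(lab) {
  n <- max(lab)
  out <- vector("list", n)
  if (n == 0L) return(out)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  r1 <- tapply(rows, l, min); r2 <- tapply(rows, l, max)
  c1 <- tapply(cols, l, min); c2 <- tapply(cols, l, max)
  for (k in as.integer(names(r1))) {
    kk <- as.character(k)
    out[[k]] <- list(rows = c(r1[[kk]], r2[[kk]]), cols = c(c1[[kk]], c2[[kk]]))
  }
  out
}
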