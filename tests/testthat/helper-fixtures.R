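# Shared fixture builders (everything is generated in code at test time).

default_field <- function(seed, n_cells = 20, ...) {
  synth_field(cell_population_spec(n_cells = n_cells, seed = seed, ...),
              frame_size_px = c(512L, 512L))
}

# rasterized disc of radius r px centred in a square frame
disc_mask <- function(r_px, pad = 6L) {
  n <- 2L * (r_px + pad) + 1L
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  (d2 <= r_px^2) * 1L
}

# rasterized axis-aligned ellipse with semi-axes a, b px
ellipse_mask <- function(a_px, b_px, pad = 6L) {
  nx <- 2L * (a_px + pad) + 1L
  ny <- 2L * (b_px + pad) + 1L
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- (seq_len(nx) - cx) / a_px
  ys <- (seq_len(ny) - cy) / b_px
  (outer(ys^2, xs^2, "+") <= 1) * 1L
}

# wrap a plain matrix as a cellmon energy map
as_map <- function(m, ps = 1) {
  structure(m, class = c("cellmon_map", "matrix"),
            pixel_size_x_um = ps, pixel_size_y_um = ps)
}

# minimal cell_labels object around a given label matrix
as_labels <- function(lab, psx = 1, psy = psx) {
  structure(
    list(label_image = lab, n_cells = max(lab),
         cells = cellmon:::label_stats(lab),
         mask = NULL, pixel_size_x_um = psx, pixel_size_y_um = psy),
    class = "cell_labels"
  )
}

# capsule rasterizer re-used for hand-built tube fixtures
capsules <- function(segments, dims_px, vs, radius_um) {
  cellmon:::rasterize_capsules(segments, dims_px, rep_len(vs, length(dims_px)),
                               radius_um)
}
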