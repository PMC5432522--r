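#' Binary tube mask with voxel calibration
#'
#' Wraps a 2-D matrix or 3-D array marking tube-like structures (capillary
#' networks, neurites) together with per-axis voxel sizes. A grayscale
#' input is binarized by Otsu before use. Anisotropic voxels (confocal
#' z-step wider than xy) are supported; 2-D images are the single-slice
#' special case.
#'
#' @param mask 2-D matrix or 3-D array; binary 0/1 or grayscale.
#' @param voxel_size_um per-axis voxel sizes `c(x, y)` or `c(x, y, z)`,
#'   recycled if scalar.
#' @return an object of class `tube_mask`.
#' @export
tube_mask <- function(mask, voxel_size_um = 1) {
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("mask must be a 2-D matrix or 3-D array", call. = FALSE)
  vs <- rep_len(voxel_size_um, nd)
  stopifnot(all(vs > 0))
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    rng <- range(mask)
    norm <- (mask - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(as.vector(norm)), range = c(0, 1))
    mask <- (norm > thr) * 1L
  }
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, voxel_size_um = vs), class = "tube_mask")
}

#' Skeletonize a tube mask
#'
#' Topology-preserving sequential thinning to a one-voxel-wide medial
#' curve skeleton (26-adjacent object / 6-adjacent background simple-point
#' deletion with curve-endpoint preservation). The number of connected
#' components is preserved. 2-D input returns a 2-D skeleton.
#'
#' @param tube a [tube_mask()] (or a plain binary matrix/array, which is
#'   wrapped with unit voxels).
#' @return binary array of the same dimensionality as the input mask.
#' @export
skeletonize_mask <- function(tube) {
  if (!inherits(tube, "tube_mask")) tube <- tube_mask(tube)
  m <- tube$mask
  was_2d <- length(dim(m)) == 2L
  if (was_2d) dim(m) <- c(dim(m), 1L)
  vs <- rep_len(tube$voxel_size_um, 3)
  if (was_2d && length(tube$voxel_size_um) == 2L) vs <- c(tube$voxel_size_um, 1)
  sk <- thin_volume_cpp(m, as.numeric(vs))
  if (was_2d) dim(sk) <- dim(sk)[1:2]
  sk
}

# 26-neighbourhood offsets as an (26 x 3) matrix of (di, dj, dk)
.offsets26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

#' Extract a spatial graph from a skeleton
#'
#' Skeleton voxels with three or more skeleton neighbours are junction
#' voxels; 26-adjacent junction voxels are merged into a single branch
#' node so a thick junction counts as one branching point. Degree-1 voxels
#' are endpoints. Edges are the paths traced between nodes; their physical
#' length is the length of the voxel polyline after light coordinate
#' smoothing (which removes the systematic overestimate of raw axial +
#' diagonal stepping on digital straight lines). Short terminal spurs
#' (rasterization whiskers) are pruned. If the pre-thinning `mask` is
#' supplied, each terminal edge is extended by the local tube radius at
#' its endpoint, compensating the tip erosion of thinning.
#'
#' @param skeleton binary matrix or 3-D array from [skeletonize_mask()].
#' @param voxel_size_um per-axis voxel sizes (`c(x, y)` or `c(x, y, z)`).
#' @param spur_min_voxels terminal edges with fewer interior voxels than
#'   this are pruned (0 disables pruning); `"auto"` scales the cutoff with
#'   the estimated tube radius (needs `mask`), since thinning whiskers are
#'   as long as the tube is thick.
#' @param mask optional original binary mask; enables radius-scaled spur
#'   pruning, radius-scaled junction merging, and (optionally) endpoint
#'   tip correction.
#' @param tip_correction extend each terminal edge by the residual tip
#'   erosion: the free distance from the skeleton endpoint to the mask
#'   background along the outward edge direction, minus the local
#'   (perpendicular) tube radius. Zero when the skeleton already reaches
#'   the centre of a rounded cap.
#' @return an object of class `network_graph`: `nodes` (tibble: node,
#'   x_um, y_um, z_um, kind, component), `edges` (tibble: edge, node_a,
#'   node_b, length_um, n_voxels, component), `voxel_size_um`.
#' @export
graph_from_skeleton <- function(skeleton, voxel_size_um = 1,
                                spur_min_voxels = "auto", mask = NULL,
                                tip_correction = TRUE) {
  m <- skeleton
  was_2d <- length(dim(m)) == 2L
  if (was_2d) dim(m) <- c(dim(m), 1L)
  vs <- rep_len(voxel_size_um, 3)
  if (was_2d && length(voxel_size_um) == 2L) vs <- c(voxel_size_um, 1)
  mask3 <- mask
  if (!is.null(mask3) && length(dim(mask3)) == 2L) dim(mask3) <- c(dim(mask3), 1L)
  g <- extract_voxel_graph(m)
  radius_um <- if (!is.null(mask3) && length(g$vox)) {
    estimate_tube_radius(mask3, g$coords, vs)
  } else min(vs)
  if (identical(spur_min_voxels, "auto")) {
    spur_min_voxels <- if (is.null(mask3)) 3L else
      max(3L, as.integer(ceiling(2.6 * radius_um / min(vs))))
  }
  if (spur_min_voxels > 0) {
    for (it in 1:4) {
      keep <- prune_spur_voxels(g, spur_min_voxels)
      if (is.null(keep)) break
      m[] <- 0L
      m[keep] <- 1L
      g <- extract_voxel_graph(m)
    }
  }
  build_network_graph(g, m, vs, mask3, was_2d, radius_um, tip_correction)
}

# Median distance from skeleton voxels to the nearest background voxel:
# a robust estimate of the tube radius (um).
estimate_tube_radius <- function(mask3, coords, vs) {
  nsamp <- min(200L, nrow(coords))
  take <- unique(as.integer(round(seq(1L, nrow(coords), length.out = nsamp))))
  r <- vapply(take, function(i) local_radius_um(mask3, coords[i, ], vs), numeric(1))
  stats::median(r)
}

# Voxel-level skeleton graph: coordinates, adjacency, degrees, node roles.
extract_voxel_graph <- function(arr) {
  d <- dim(arr)
  vox <- which(arr > 0L)
  nv <- length(vox)
  if (nv == 0L) {
    return(list(vox = integer(), coords = matrix(0, 0, 3), adj = list(),
                deg = integer(), dim = d))
  }
  co <- arrayInd(vox, d)                      # (row i, col j, slice k)
  id_of <- array(0L, d)
  id_of[vox] <- seq_len(nv)
  adj <- vector("list", nv)
  for (v in seq_len(nv)) adj[[v]] <- integer(0)
  for (o in seq_len(nrow(.offsets26))) {
    di <- .offsets26[o, 1]; dj <- .offsets26[o, 2]; dk <- .offsets26[o, 3]
    ii <- co[, 1] + di; jj <- co[, 2] + dj; kk <- co[, 3] + dk
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    nb <- integer(nv)
    nb[ok] <- id_of[cbind(ii[ok], jj[ok], kk[ok])]
    hit <- which(nb > 0L)
    for (v in hit) adj[[v]] <- c(adj[[v]], nb[v])
  }
  deg <- lengths(adj)
  list(vox = vox, coords = co, adj = adj, deg = deg, dim = d)
}

# Indices (into the array) of voxels to keep after removing terminal spurs;
# NULL when there is nothing to prune.
prune_spur_voxels <- function(g, min_voxels) {
  if (!length(g$vox)) return(NULL)
  node <- g$deg != 2L
  drop <- rep(FALSE, length(g$vox))
  found <- FALSE
  for (v in which(g$deg == 1L)) {
    path <- v
    prev <- 0L
    cur <- v
    repeat {
      nxt <- setdiff(g$adj[[cur]], prev)
      if (length(nxt) != 1L) break
      prev <- cur
      cur <- nxt
      if (node[cur]) break
      path <- c(path, cur)
      if (length(path) > min_voxels) break
    }
    # spur: short terminal path hanging off a junction voxel
    if (g$deg[cur] >= 3L && length(path) <= min_voxels) {
      drop[path] <- TRUE
      found <- TRUE
    }
  }
  if (!found) return(NULL)
  g$vox[!drop]
}

build_network_graph <- function(g, arr, vs, mask, was_2d, radius_um = min(vs),
                                tip_correction = FALSE) {
  nv <- length(g$vox)
  empty_nodes <- tibble::tibble(node = integer(), x_um = numeric(),
                                y_um = numeric(), z_um = numeric(),
                                kind = character(), component = integer())
  empty_edges <- tibble::tibble(edge = integer(), node_a = integer(),
                                node_b = integer(), length_um = numeric(),
                                n_voxels = integer(), component = integer())
  if (nv == 0L) {
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          voxel_size_um = if (was_2d) vs[1:2] else vs),
                     class = "network_graph"))
  }
  deg <- g$deg
  is_node_vox <- deg != 2L
  # physical coordinates of every skeleton voxel (needed for clustering)
  xyz_all <- cbind((g$coords[, 2] - 0.5) * vs[1],
                   (g$coords[, 1] - 0.5) * vs[2],
                   (g$coords[, 3] - 0.5) * vs[3])
  # cluster junction voxels into branch nodes by single linkage within a
  # merge radius that scales with the tube thickness: the medial axis of a
  # thick junction fans out over a ball of about the tube radius, and the
  # paper-level quantity is branching points, not junction voxels
  node_id <- integer(nv)
  jv <- which(deg >= 3L)
  next_node <- 0L
  if (length(jv)) {
    merge_r <- max(2 * radius_um, sqrt(sum(vs^2)) + 1e-9)
    pj <- xyz_all[jv, , drop = FALSE]
    dj <- as.matrix(stats::dist(pj)) <= merge_r
    gi <- igraph::graph_from_adjacency_matrix(dj, mode = "undirected", diag = FALSE)
    cl <- igraph::components(gi)$membership
    node_id[jv] <- as.integer(cl)
    next_node <- max(cl)
  }
  branch_nodes <- next_node
  for (v in which(deg == 1L | deg == 0L)) {
    next_node <- next_node + 1L
    node_id[v] <- next_node
  }
  n_nodes <- next_node
  kind <- c(rep("branch", branch_nodes), rep("endpoint", n_nodes - branch_nodes))
  xyz <- xyz_all
  node_xyz <- matrix(0, n_nodes, 3)
  for (nid in seq_len(n_nodes)) {
    node_xyz[nid, ] <- colMeans(xyz[node_id == nid, , drop = FALSE])
  }

  # trace edges between node voxels across degree-2 chains
  visited_path <- rep(FALSE, nv)
  edges <- list()
  seen_pair <- character(0)
  add_edge <- function(a, b, path_vox) {
    poly <- xyz[path_vox, , drop = FALSE]
    len <- polyline_length(poly)
    edges[[length(edges) + 1L]] <<- list(node_a = a, node_b = b, len = len,
                                         nvox = length(path_vox),
                                         end_vox = path_vox[c(1, length(path_vox))],
                                         path = path_vox)
  }
  for (v in which(is_node_vox & deg >= 1L)) {
    for (u in g$adj[[v]]) {
      if (is_node_vox[u]) {
        if (node_id[u] == node_id[v] && deg[v] >= 3L) next  # intra-cluster link
        key <- paste(sort(c(v, u)), collapse = "-")
        if (key %in% seen_pair) next
        seen_pair <- c(seen_pair, key)
        add_edge(node_id[v], node_id[u], c(v, u))
      } else {
        if (visited_path[u]) next
        path <- c(v, u)
        visited_path[u] <- TRUE
        prev <- v; cur <- u
        repeat {
          nxt <- setdiff(g$adj[[cur]], prev)
          if (length(nxt) == 0L) break
          nxt <- nxt[1]
          path <- c(path, nxt)
          if (is_node_vox[nxt]) break
          visited_path[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        last <- path[length(path)]
        if (is_node_vox[last]) {
          add_edge(node_id[v], node_id[last], path)
        } else {
          # closed loop without any node voxel
          add_edge(node_id[v], node_id[v], path)
        }
      }
    }
  }
  # pure cycles with no node voxel at all (every voxel degree 2)
  remaining <- which(!visited_path & deg == 2L & node_id == 0L)
  while (length(remaining)) {
    start <- remaining[1]
    next_node <- next_node + 1L
    node_id[start] <- next_node
    kind <- c(kind, "loop")
    node_xyz <- rbind(node_xyz, xyz[start, ])
    path <- start
    visited_path[start] <- TRUE
    prev <- 0L; cur <- start
    repeat {
      nxt <- setdiff(g$adj[[cur]], prev)
      nxt <- nxt[!visited_path[nxt] | nxt == start]
      if (length(nxt) == 0L) break
      nxt <- nxt[1]
      path <- c(path, nxt)
      if (nxt == start) break
      visited_path[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    add_edge(next_node, next_node, path)
    remaining <- which(!visited_path & deg == 2L & node_id == 0L)
  }
  n_nodes <- next_node

  edge_tbl <- if (length(edges)) {
    tibble::tibble(
      edge = seq_along(edges),
      node_a = vapply(edges, `[[`, numeric(1), "node_a"),
      node_b = vapply(edges, `[[`, numeric(1), "node_b"),
      length_um = vapply(edges, `[[`, numeric(1), "len"),
      n_voxels = vapply(edges, function(e) as.integer(e$nvox), integer(1))
    )
  } else empty_edges[, 1:5]

  # junction interior surgery, iterated to a fixed point (contracting a
  # fragmented junction can expose a new short self-loop and vice versa):
  # self-loops shorter than ~2*pi*r cannot be real vessels (a tube of
  # radius r cannot close a loop tighter than its own bending limit) and
  # are dropped as thinning artifacts of thick junctions; short
  # branch-branch edges are junction interior, kept in the totals but not
  # as capillary segments; nodes with two incident edges are bends, fused
  # into one segment.
  absorbed_um <- 0
  if (nrow(edge_tbl)) {
    is_branchy <- function(nd) nd <= length(kind) & kind[nd] %in% c("branch")
    for (pass in 1:20) {
      changed <- FALSE
      # drop short self-loops at junctions
      is_loop <- edge_tbl$node_a == edge_tbl$node_b &
        is_branchy(edge_tbl$node_a) &
        edge_tbl$length_um < 7 * radius_um
      if (any(is_loop)) {
        edge_tbl <- edge_tbl[!is_loop, , drop = FALSE]
        edges <- edges[!is_loop]
        changed <- TRUE
      }
      # contract short branch-branch edges (fragmented junctions)
      repeat {
        bb_e <- which(edge_tbl$node_a != edge_tbl$node_b &
                      is_branchy(edge_tbl$node_a) &
                      is_branchy(edge_tbl$node_b) &
                      edge_tbl$length_um < 2.5 * radius_um)
        if (!length(bb_e)) break
        e1 <- bb_e[1]
        a <- edge_tbl$node_a[e1]; b <- edge_tbl$node_b[e1]
        absorbed_um <- absorbed_um + edge_tbl$length_um[e1]
        edge_tbl <- edge_tbl[-e1, , drop = FALSE]
        edges <- edges[-e1]
        edge_tbl$node_a[edge_tbl$node_a == b] <- a
        edge_tbl$node_b[edge_tbl$node_b == b] <- a
        node_xyz[a, ] <- (node_xyz[a, ] + node_xyz[b, ]) / 2
        kind[b] <- "merged"
        changed <- TRUE
      }
      # dissolve elbows: a node with exactly two incident edges is a bend
      # in one capillary segment, not a branch or endpoint
      repeat {
        inc <- c(edge_tbl$node_a, edge_tbl$node_b)
        degn <- tabulate(inc, nbins = length(kind))
        has_loop <- vapply(seq_along(kind), function(nd) {
          any(edge_tbl$node_a == nd & edge_tbl$node_b == nd)
        }, logical(1))
        elbow <- which(degn == 2L & kind %in% c("branch", "endpoint") & !has_loop)
        if (!length(elbow)) break
        nd <- elbow[1]
        ei <- which(edge_tbl$node_a == nd | edge_tbl$node_b == nd)
        if (length(ei) == 1L) {
          # both ends of one edge meet here: it has become a self-loop
          edge_tbl$node_a[ei] <- nd
          edge_tbl$node_b[ei] <- nd
          next
        }
        other <- vapply(ei, function(e) {
          if (edge_tbl$node_a[e] == nd) edge_tbl$node_b[e] else edge_tbl$node_a[e]
        }, numeric(1))
        end_far <- vapply(seq_along(ei), function(i) {
          e <- ei[i]
          edges[[e]]$end_vox[if (edge_tbl$node_a[e] == nd) 2 else 1]
        }, numeric(1))
        keep_e <- ei[1]
        edge_tbl$node_a[keep_e] <- other[1]
        edge_tbl$node_b[keep_e] <- other[2]
        edge_tbl$length_um[keep_e] <- sum(edge_tbl$length_um[ei])
        edge_tbl$n_voxels[keep_e] <- sum(edge_tbl$n_voxels[ei]) - 1L
        edges[[keep_e]]$end_vox <- end_far
        edge_tbl <- edge_tbl[-ei[2], , drop = FALSE]
        edges <- edges[-ei[2]]
        kind[nd] <- "merged"
        changed <- TRUE
      }
      if (!changed) break
    }
    # a junction that lost its artifact arms (dropped loops, pruned
    # whiskers) is structurally a segment end
    inc <- c(edge_tbl$node_a, edge_tbl$node_b)
    degn <- tabulate(inc, nbins = length(kind))
    kind[kind == "branch" & degn <= 1L] <- "endpoint"
  }

  # bridge each edge across its junction: polylines stop at the voxel
  # adjacent to the branch cluster, so add the gap to the node centroid
  if (nrow(edge_tbl)) {
    for (e in seq_along(edges)) {
      for (side in c("node_a", "node_b")) {
        nid <- edge_tbl[[side]][e]
        if (nid <= length(kind) && kind[nid] == "branch") {
          vx <- edges[[e]]$end_vox[if (side == "node_a") 1 else 2]
          gap <- sqrt(sum((xyz[vx, ] - node_xyz[nid, ])^2))
          edge_tbl$length_um[e] <- edge_tbl$length_um[e] + gap
        }
      }
    }
  }

  # tip correction: if thinning eroded a tip, the free distance from the
  # skeleton endpoint to the background along the outward edge direction
  # exceeds the perpendicular tube radius; extend by the difference
  if (isTRUE(tip_correction) && !is.null(mask) && nrow(edge_tbl)) {
    mm <- mask
    if (length(dim(mm)) == 2L) dim(mm) <- c(dim(mm), 1L)
    for (e in seq_along(edges)) {
      pth <- edges[[e]]$path
      if (is.null(pth) || length(pth) < 2L) next
      for (side in c("node_a", "node_b")) {
        nid <- edge_tbl[[side]][e]
        if (nid <= length(kind) && kind[nid] == "endpoint") {
          tipv <- if (side == "node_a") pth[1] else pth[length(pth)]
          refv <- if (side == "node_a") pth[min(5L, length(pth))] else
            pth[max(1L, length(pth) - 4L)]
          if (tipv == refv) next
          p_tip <- xyz[tipv, ]
          dirv <- p_tip - xyz[refv, ]
          dirv <- dirv / sqrt(sum(dirv^2))
          axial <- axial_free_um(mm, p_tip, dirv, vs)
          perp <- local_radius_um(mm, g$coords[tipv, ], vs)
          edge_tbl$length_um[e] <- edge_tbl$length_um[e] +
            min(max(axial - perp, 0), 2 * radius_um)
        }
      }
    }
  }

  # drop nodes swallowed by junction merging and relabel compactly
  alive <- which(kind != "merged")
  remap <- integer(n_nodes)
  remap[alive] <- seq_along(alive)
  if (nrow(edge_tbl)) {
    edge_tbl$node_a <- remap[edge_tbl$node_a]
    edge_tbl$node_b <- remap[edge_tbl$node_b]
    edge_tbl$edge <- seq_len(nrow(edge_tbl))
  }
  node_xyz <- node_xyz[alive, , drop = FALSE]
  kind <- kind[alive]
  n_nodes <- length(alive)
  node_tbl <- tibble::tibble(
    node = seq_len(n_nodes),
    x_um = node_xyz[, 1], y_um = node_xyz[, 2], z_um = node_xyz[, 3],
    kind = kind
  )
  # connected components over the node/edge graph
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(edge_tbl)) data.frame(from = edge_tbl$node_a, to = edge_tbl$node_b) else
      data.frame(from = integer(), to = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes))
  )
  comp <- igraph::components(ig)$membership
  node_tbl$component <- as.integer(comp[as.character(node_tbl$node)])
  edge_tbl$component <- if (nrow(edge_tbl)) node_tbl$component[edge_tbl$node_a] else integer(0)
  structure(list(nodes = node_tbl, edges = edge_tbl,
                 absorbed_junction_um = absorbed_um,
                 tube_radius_um = radius_um,
                 voxel_size_um = if (was_2d) vs[1:2] else vs),
            class = "network_graph")
}

# Polyline length after light coordinate smoothing (running mean, window 5,
# endpoints fixed); removes the stair-step overestimate of digital lines.
polyline_length <- function(poly) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  if (n > 4L) {
    sm <- poly
    for (c in 1:3) {
      x <- poly[, c]
      cs <- cumsum(c(0, x))
      w <- 2L
      i <- seq_len(n)
      lo <- pmax(i - w, 1L); hi <- pmin(i + w, n)
      sm[, c] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    sm[1, ] <- poly[1, ]; sm[n, ] <- poly[n, ]
    poly <- sm
  }
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-n, , drop = FALSE])^2)))
}

# Free distance (um) from a point along a direction until the mask
# background is reached (sampled at sub-voxel steps).
axial_free_um <- function(arr, p_um, dir, vs, max_um = 60) {
  d <- dim(arr)
  step <- 0.4 * min(vs)
  t <- step
  while (t <= max_um) {
    q <- p_um + t * dir
    i <- ceiling(q[2] / vs[2]); j <- ceiling(q[1] / vs[1]); k <- ceiling(q[3] / vs[3])
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) return(t)
    if (arr[i, j, k] == 0L) return(t)
    t <- t + step
  }
  max_um
}

# Distance (um) from a skeleton voxel to the nearest background voxel.
local_radius_um <- function(arr, ijk, vs, max_r_vox = 25L) {
  d <- dim(arr)
  i1 <- max(1L, ijk[1] - max_r_vox); i2 <- min(d[1], ijk[1] + max_r_vox)
  j1 <- max(1L, ijk[2] - max_r_vox); j2 <- min(d[2], ijk[2] + max_r_vox)
  k1 <- max(1L, ijk[3] - max_r_vox); k2 <- min(d[3], ijk[3] + max_r_vox)
  sub <- arr[i1:i2, j1:j2, k1:k2, drop = FALSE]
  bg <- which(sub == 0L)
  if (!length(bg)) return(max_r_vox * min(vs))
  co <- arrayInd(bg, dim(sub))
  dx <- (co[, 2] - (ijk[2] - j1 + 1L)) * vs[1]
  dy <- (co[, 1] - (ijk[1] - i1 + 1L)) * vs[2]
  dz <- (co[, 3] - (ijk[3] - k1 + 1L)) * vs[3]
  min(sqrt(dx^2 + dy^2 + dz^2))
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes (%d branch, %d endpoint), %d edges, total %.1f um\n",
              nrow(x$nodes), sum(x$nodes$kind == "branch"),
              sum(x$nodes$kind == "endpoint"), nrow(x$edges),
              sum(x$edges$length_um)))
  invisible(x)
}

#' Summary metrics of a capillary network graph
#'
#' @param graph a [graph_from_skeleton()] result.
#' @return a one-row tibble: `total_length_um`, `mean_segment_length_um`,
#'   `n_branch_points`, `n_edges`, `n_endpoints`, `n_components`,
#'   `n_isolated` (components without any edge, i.e. cells that stayed as
#'   single dots).
#' @export
capillary_metrics <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  e <- graph$edges; n <- graph$nodes
  n_comp <- if (nrow(n)) max(n$component) else 0L
  with_edges <- unique(e$component)
  tibble::tibble(
    total_length_um = sum(e$length_um) + (graph$absorbed_junction_um %||% 0),
    mean_segment_length_um = if (nrow(e)) mean(e$length_um) else 0,
    n_branch_points = sum(n$kind == "branch"),
    n_edges = nrow(e),
    n_endpoints = sum(n$kind == "endpoint"),
    n_components = n_comp,
    n_isolated = n_comp - length(with_edges)
  )
}

#' Full tube-network analysis
#'
#' Convenience wrapper: [skeletonize_mask()], [graph_from_skeleton()] with
#' tip correction against the input mask, and [capillary_metrics()].
#'
#' @param tube a [tube_mask()] or binary matrix/array.
#' @param voxel_size_um per-axis voxel sizes (used when `tube` is a bare
#'   array).
#' @param spur_min_voxels see [graph_from_skeleton()].
#' @return a list with `graph` and `metrics`.
#' @export
analyze_network <- function(tube, voxel_size_um = 1, spur_min_voxels = "auto",
                            tip_correction = TRUE) {
  if (!inherits(tube, "tube_mask")) tube <- tube_mask(tube, voxel_size_um)
  sk <- skeletonize_mask(tube)
  gr <- graph_from_skeleton(sk, tube$voxel_size_um,
                            spur_min_voxels = spur_min_voxels,
                            mask = tube$mask,
                            tip_correction = tip_correction)
  list(graph = gr, metrics = capillary_metrics(gr))
}
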