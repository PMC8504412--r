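# programmatic fixtures shared across test files

# filled cylinder along z
make_cylinder <- function(dimv, center_xy, radius, z_range, value = TRUE) {
  a <- array(if (is.logical(value)) FALSE else 0, dimv)
  xs <- matrix(seq_len(dimv[1]), dimv[1], dimv[2])
  ys <- matrix(seq_len(dimv[2]), dimv[1], dimv[2], byrow = TRUE)
  disk <- (xs - center_xy[1])^2 + (ys - center_xy[2])^2 <= radius^2
  for (z in z_range[1]:z_range[2]) a[, , z][disk] <- value
  a
}

# voxel-line helpers: build a logical array from a coordinate matrix
line_array <- function(coords, dimv) {
  a <- array(FALSE, dimv)
  a[coords] <- TRUE
  a
}

# a Y of three straight arms meeting at (c, c, c)
make_y_lines <- function(n_arm = 6L, dimv = c(20L, 20L, 20L)) {
  c0 <- 10L
  arm1 <- cbind(c0, c0, c0 - seq_len(n_arm))            # down z
  arm2 <- cbind(c0 + seq_len(n_arm), c0, c0 + seq_len(n_arm)) # diagonal
  arm3 <- cbind(c0 - seq_len(n_arm), c0, c0 + seq_len(n_arm)) # diagonal
  rbind(cbind(c0, c0, c0), arm1, arm2, arm3)
}

# uniform plug-flow acquisition: constant magnitude, spatially uniform
# per-frame velocity (u_j along a chosen axis)
make_uniform_flow <- function(dimv = c(12L, 12L, 12L), u = NULL, M = 5L,
                              axis = 3L, venc = 110, voxel_size = 1) {
  if (is.null(u)) u <- seq(5, 25, length.out = M)
  M <- length(u)
  mk <- function(vals) {
    a <- array(0, c(dimv, M))
    for (j in seq_len(M)) a[, , , j] <- vals[j]
    a
  }
  zero <- rep(0, M)
  flow_volume(
    magnitude = array(1, c(dimv, M)),
    vx = mk(if (axis == 1L) u else zero),
    vy = mk(if (axis == 2L) u else zero),
    vz = mk(if (axis == 3L) u else zero),
    venc = venc, voxel_size = voxel_size, period = 1)
}

# independent Dijkstra oracle on a tree's edge list (pure R, O(n^2))
dijkstra_oracle <- function(n, edges, sources) {
  dist <- rep(Inf, n)
  dist[sources] <- 0
  visited <- rep(FALSE, n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]; w <- edges$length_mm[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    if (!is.null(adj[[u]])) for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# random 26-connected voxel tree grown by attaching steps to random nodes
random_voxel_tree <- function(n_voxels, dimv = c(40L, 40L, 40L), seed = 1) {
  set.seed(seed)
  pts <- matrix(c(20L, 20L, 20L), 1L, 3L)
  occ <- new.env()
  occ[[paste(pts[1, ], collapse = ",")]] <- TRUE
  while (nrow(pts) < n_voxels) {
    base <- pts[sample.int(nrow(pts), 1L), ]
    step <- sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
    if (all(step == 0L)) next
    q <- base + step
    if (any(q < 1L) || any(q > dimv)) next
    key <- paste(q, collapse = ",")
    if (!is.null(occ[[key]])) next
    occ[[key]] <- TRUE
    pts <- rbind(pts, q)
  }
  pts
}
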