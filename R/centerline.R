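#' Skeletonize a vessel mask
#'
#' Reduces a binary vascular mask to a one-voxel-wide centerline by
#' topology-preserving sequential 3D thinning (simple-point deletion under
#' 26-connectivity for the object, with directional border subcycles).
#' Because thinning erodes tube end caps by roughly one radius, each skeleton
#' endpoint is optionally re-grown along its local direction while still
#' inside the mask, restoring the centerline to the full tube length.
#'
#' @param mask logical 3D array (a `vessel_mask` or any binary volume).
#' @param extend_ends re-grow skeleton endpoints to the mask boundary
#'   (default `TRUE`).
#' @return Logical 3D array (skeleton voxels), subset of `mask`, with the
#'   `voxel_size` attribute carried over.
#' @export
skeletonize <- function(mask, extend_ends = TRUE) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stopf("`mask` must be a 3D array")
  m <- array(as.logical(mask), d)
  m[is.na(m)] <- FALSE
  if (!any(m)) stopf("mask is empty", class = "cerebropwv_empty_mask")
  sk <- cpp_thin3(m, d)
  if (extend_ends) sk <- extend_skeleton_ends(sk, m)
  structure(sk, voxel_size = attr(mask, "voxel_size"))
}

# 26-neighborhood offsets as a 26 x 3 integer matrix
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# count skeleton neighbors of every voxel (26-connectivity) via array shifts
neighbor_count <- function(sk) {
  d <- dim(sk)
  cnt <- array(0L, d)
  off <- offsets26()
  ski <- array(as.integer(sk), d)
  for (r in seq_len(nrow(off))) {
    sx <- off[r, 1L]; sy <- off[r, 2L]; sz <- off[r, 3L]
    xs <- seq_len(d[1L]); ys <- seq_len(d[2L]); zs <- seq_len(d[3L])
    xd <- xs + sx; yd <- ys + sy; zd <- zs + sz
    okx <- xd >= 1L & xd <= d[1L]; oky <- yd >= 1L & yd <= d[2L]; okz <- zd >= 1L & zd <= d[3L]
    cnt[xs[okx], ys[oky], zs[okz]] <- cnt[xs[okx], ys[oky], zs[okz]] +
      ski[xd[okx], yd[oky], zd[okz]]
  }
  cnt
}

# step each endpoint outward along its local direction while inside the mask
extend_skeleton_ends <- function(sk, mask) {
  d <- dim(sk)
  cnt <- neighbor_count(sk)
  ends <- which(sk & cnt == 1L, arr.ind = TRUE)
  if (nrow(ends) == 0L) return(sk)
  off <- offsets26()
  for (r in seq_len(nrow(ends))) {
    p <- ends[r, ]
    # the unique neighbor defines the inward direction
    nb <- NULL
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      if (all(q >= 1L) && all(q <= d) && sk[q[1L], q[2L], q[3L]]) { nb <- q; break }
    }
    if (is.null(nb)) next
    step <- p - nb
    cur <- p
    repeat {
      nxt <- cur + step
      if (any(nxt < 1L) || any(nxt > d)) break
      if (!mask[nxt[1L], nxt[2L], nxt[3L]]) break
      if (sk[nxt[1L], nxt[2L], nxt[3L]]) break
      sk[nxt[1L], nxt[2L], nxt[3L]] <- TRUE
      cur <- nxt
    }
  }
  sk
}

#' Build a branch-labeled centerline tree
#'
#' Converts a skeleton into a graph representation: voxels become nodes with
#' physical coordinates, 26-adjacency becomes weighted edges (Euclidean step
#' length in mm), node kinds are assigned from the neighbor count (endpoint
#' = 1, interior = 2, junction >= 3), and maximal junction-free paths receive
#' branch labels. Junction voxels belong to no branch. Short spur branches
#' (fewer than `spur_min_voxels` voxels, touching an endpoint) are thinning
#' artifacts and are pruned by default.
#'
#' @param skeleton logical 3D array from [skeletonize()], or an integer
#'   matrix of voxel coordinates (one row per voxel).
#' @param voxel_size voxel size in mm (scalar or 3-vector).
#' @param prune_spurs prune short endpoint spurs (default `TRUE`).
#' @param spur_min_voxels minimum branch voxel count kept during pruning.
#' @param dim grid dimensions, required when `skeleton` is a coordinate
#'   matrix.
#' @return An object of class `centerline_tree`: a list with `nodes` (tibble:
#'   `node_id`, voxel indices `i, j, k`, coordinates `x, y, z` in mm,
#'   `degree`, `node_kind`, `branch_id`), `edges` (tibble: `from`, `to`,
#'   `length_mm`), `dim`, and `voxel_size`.
#' @export
build_tree <- function(skeleton, voxel_size = NULL, prune_spurs = TRUE,
                       spur_min_voxels = 3L, dim = NULL) {
  if (is.matrix(skeleton)) {
    if (is.null(dim)) dim <- apply(skeleton, 2L, max) + 1L
    arr <- array(FALSE, dim)
    arr[skeleton] <- TRUE
    skeleton <- arr
  }
  voxel_size <- vec3(voxel_size %||% attr(skeleton, "voxel_size") %||% 1)
  tree <- tree_from_array(skeleton, voxel_size)
  if (prune_spurs) tree <- prune_short_spurs(tree, spur_min_voxels)
  tree
}

# core: voxel array -> labeled tree
tree_from_array <- function(sk, voxel_size) {
  d <- dim(sk)
  vox <- which(sk, arr.ind = TRUE)
  if (nrow(vox) == 0L) stopf("skeleton is empty", class = "cerebropwv_empty_tree")
  n <- nrow(vox)
  id_arr <- array(0L, d)
  id_arr[vox] <- seq_len(n)
  # adjacency via the 13 positive half-offsets
  off <- offsets26()
  off <- off[order(off[, 3L], off[, 2L], off[, 1L]), , drop = FALSE]
  half <- off[seq_len(13L), , drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(half))) {
    o <- half[r, ]
    q <- sweep(vox, 2L, o, "+")
    ok <- q[, 1L] >= 1L & q[, 1L] <= d[1L] &
          q[, 2L] >= 1L & q[, 2L] <= d[2L] &
          q[, 3L] >= 1L & q[, 3L] <= d[3L]
    if (!any(ok)) next
    tgt <- id_arr[q[ok, , drop = FALSE]]
    hit <- tgt > 0L
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, tgt[hit])
    len <- c(len, rep(sqrt(sum((o * voxel_size)^2)), sum(hit)))
  }
  edges <- tibble(from = from, to = to, length_mm = len)
  degree <- tabulate(c(edges$from, edges$to), nbins = n)
  node_kind <- ifelse(degree >= 3L, "junction",
                      ifelse(degree == 2L, "interior", "endpoint"))
  nodes <- tibble(
    node_id = seq_len(n),
    i = as.integer(vox[, 1L]), j = as.integer(vox[, 2L]), k = as.integer(vox[, 3L]),
    x = (vox[, 1L] - 1) * voxel_size[1L],
    y = (vox[, 2L] - 1) * voxel_size[2L],
    z = (vox[, 3L] - 1) * voxel_size[3L],
    degree = as.integer(degree),
    node_kind = node_kind,
    branch_id = NA_integer_)
  # branch labels: connected components after removing junction voxels
  nonj <- nodes$node_id[nodes$node_kind != "junction"]
  if (length(nonj) > 0L) {
    keep <- edges$from %in% nonj & edges$to %in% nonj
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$from[keep]),
                 to = as.character(edges$to[keep])),
      directed = FALSE,
      vertices = data.frame(name = as.character(nonj)))
    comp <- igraph::components(g)$membership
    nodes$branch_id[match(as.integer(names(comp)), nodes$node_id)] <-
      as.integer(comp)
  }
  structure(list(nodes = nodes, edges = edges, dim = d, voxel_size = voxel_size),
            class = "centerline_tree")
}

prune_short_spurs <- function(tree, spur_min_voxels) {
  nd <- tree$nodes
  drop <- integer(0)
  for (b in unique(stats::na.omit(nd$branch_id))) {
    members <- nd$node_id[!is.na(nd$branch_id) & nd$branch_id == b]
    if (length(members) < spur_min_voxels &&
        any(nd$node_kind[match(members, nd$node_id)] == "endpoint"))
      drop <- c(drop, members)
  }
  if (length(drop) == 0L) return(tree)
  rebuild_tree(tree, setdiff(nd$node_id, drop), allow_empty = FALSE)
}

# rebuild a tree from a surviving node-id set (re-deriving adjacency, kinds
# and branch labels); junction voxels left with no surviving neighbor are
# dropped
rebuild_tree <- function(tree, keep_ids, allow_empty = FALSE) {
  nd <- tree$nodes[tree$nodes$node_id %in% keep_ids, ]
  if (nrow(nd) == 0L) {
    if (allow_empty) stopf("selection removed every centerline voxel",
                           class = "cerebropwv_empty_tree")
    stopf("selection removed every centerline voxel",
          class = "cerebropwv_empty_tree")
  }
  arr <- array(FALSE, tree$dim)
  arr[cbind(nd$i, nd$j, nd$k)] <- TRUE
  out <- tree_from_array(arr, tree$voxel_size)
  # drop isolated former-junction voxels (degree 0 after selection)
  if (any(out$nodes$degree == 0L) && nrow(out$nodes) > 1L) {
    keep <- out$nodes$node_id[out$nodes$degree > 0L]
    if (length(keep) > 0L && length(keep) < nrow(out$nodes)) {
      arr2 <- array(FALSE, out$dim)
      nd2 <- out$nodes[out$nodes$node_id %in% keep, ]
      arr2[cbind(nd2$i, nd2$j, nd2$k)] <- TRUE
      out <- tree_from_array(arr2, out$voxel_size)
    }
  }
  out
}

#' @export
print.centerline_tree <- function(x, ...) {
  kinds <- table(x$nodes$node_kind)
  cat(sprintf("<centerline_tree> %d voxels, %d branches (%s)\n",
              nrow(x$nodes), length(unique(stats::na.omit(x$nodes$branch_id))),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  if ("distance_mm" %in% names(x$nodes))
    cat(sprintf("  distances: %.1f-%.1f mm (%d reachable)\n",
                min(x$nodes$distance_mm, na.rm = TRUE),
                max(x$nodes$distance_mm, na.rm = TRUE),
                sum(x$nodes$reachable)))
  invisible(x)
}

#' Count topological junctions of a centerline tree
#'
#' Voxel-level thinning can represent one anatomical bifurcation as a small
#' cluster of mutually adjacent junction-flagged voxels; the topological
#' junction count is the number of connected clusters.
#'
#' @param tree a `centerline_tree`.
#' @return Integer number of junction clusters.
#' @export
count_junctions <- function(tree) {
  jn <- tree$nodes$node_id[tree$nodes$node_kind == "junction"]
  if (length(jn) == 0L) return(0L)
  keep <- tree$edges$from %in% jn & tree$edges$to %in% jn
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(tree$edges$from[keep]),
               to = as.character(tree$edges$to[keep])),
    directed = FALSE, vertices = data.frame(name = as.character(jn)))
  igraph::components(g)$no
}

#' Keep or remove centerline branches by region or label
#'
#' Programmatic counterpart of manual vessel cropping: branches are selected
#' either by a 3D region (logical array) or by explicit branch ids, and then
#' kept or removed. A branch matches a region when `rule` of its voxels fall
#' inside (`"any"`, `"all"`, or `"majority"`). After selection the surviving
#' voxels are relabeled and node kinds recomputed, so a former junction whose
#' third arm was removed becomes an interior voxel and its two remaining arms
#' merge into one branch.
#'
#' @param tree a `centerline_tree`.
#' @param region logical 3D array (same grid) or integer vector of branch ids.
#' @param mode `"remove"` (default) or `"keep"`.
#' @param rule branch membership test for array regions.
#' @return A relabeled `centerline_tree`.
#' @export
select_branches <- function(tree, region, mode = c("remove", "keep"),
                            rule = c("any", "all", "majority")) {
  stopifnot(inherits(tree, "centerline_tree"))
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  nd <- tree$nodes
  if (is.array(region)) {
    if (!identical(dim(region), tree$dim))
      stopf("region grid (%s) does not match the tree grid (%s)",
            paste(dim(region), collapse = "x"), paste(tree$dim, collapse = "x"))
    inside <- region[cbind(nd$i, nd$j, nd$k)]
    inside[is.na(inside)] <- FALSE
    hit <- tapply(inside[!is.na(nd$branch_id)],
                  nd$branch_id[!is.na(nd$branch_id)],
                  switch(rule,
                         any = any,
                         all = all,
                         majority = function(x) mean(x) > 0.5))
    sel <- as.integer(names(hit))[unlist(hit)]
  } else {
    sel <- as.integer(region)
  }
  branch_sel <- !is.na(nd$branch_id) & nd$branch_id %in% sel
  if (mode == "remove") {
    if (!any(branch_sel)) return(tree)   # empty removal region: identity
    keep_ids <- nd$node_id[!branch_sel]
    # junctions survive only with a surviving branch neighbor
  } else {
    keep_ids <- nd$node_id[branch_sel]
  }
  if (length(keep_ids) == 0L)
    stopf("selection removed every centerline voxel",
          class = "cerebropwv_empty_tree")
  rebuild_tree(tree, keep_ids)
}
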