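#' Assign vascular path distances from root seed(s)
#'
#' Step-wise distance assignment along the centerline: multi-source shortest
#' paths over the skeleton adjacency with edge weight equal to the physical
#' Euclidean step between adjacent voxels. With several seeds (e.g. the most
#' proximal voxel of each internal carotid artery) every voxel keeps the
#' shorter distance, mirroring the two candidate routes through the Circle of
#' Willis. Voxels with no path to any seed are flagged unreachable; spurs not
#' connected to a seed thereby obtain no distance and are excluded downstream.
#'
#' @param tree a `centerline_tree`.
#' @param seeds seed voxels: an integer matrix (rows of `i, j, k` voxel
#'   indices, 1-based), a list of such triples, or a vector of node ids.
#' @return The tree with node columns `distance_mm` (NA when unreachable),
#'   `seed_id` (which seed produced the kept minimum) and `reachable`, plus a
#'   `seeds` element recording the seed node ids.
#' @export
assign_distances <- function(tree, seeds) {
  stopifnot(inherits(tree, "centerline_tree"))
  seed_ids <- resolve_seeds(tree, seeds)
  g <- tree_graph(tree)
  dm <- igraph::distances(g, v = as.character(seed_ids), weights = igraph::E(g)$length_mm)
  # dm: seeds x nodes, columns ordered as igraph vertices (node_id order)
  node_order <- as.integer(igraph::V(g)$name)
  dmin <- unname(apply(dm, 2L, min))
  which_seed <- unname(apply(dm, 2L, which.min))
  nd <- tree$nodes
  idx <- match(nd$node_id, node_order)
  nd$distance_mm <- ifelse(is.finite(dmin[idx]), dmin[idx], NA_real_)
  nd$seed_id <- ifelse(is.finite(dmin[idx]), seed_ids[which_seed[idx]], NA_integer_)
  nd$reachable <- is.finite(dmin[idx])
  if (!any(nd$reachable))
    stopf("no centerline voxel is reachable from the seed(s)",
          class = "cerebropwv_unreachable")
  tree$nodes <- nd
  tree$seeds <- seed_ids
  tree
}

resolve_seeds <- function(tree, seeds) {
  nd <- tree$nodes
  if (is.list(seeds) && !is.data.frame(seeds))
    seeds <- do.call(rbind, lapply(seeds, as.integer))
  if (is.matrix(seeds)) {
    ids <- integer(nrow(seeds))
    for (r in seq_len(nrow(seeds))) {
      hit <- which(nd$i == seeds[r, 1L] & nd$j == seeds[r, 2L] & nd$k == seeds[r, 3L])
      if (length(hit) == 0L)
        stopf("seed (%s) does not lie on the centerline",
              paste(seeds[r, ], collapse = ", "),
              class = "cerebropwv_bad_seed")
      ids[r] <- nd$node_id[hit[1L]]
    }
  } else {
    ids <- as.integer(seeds)
    bad <- setdiff(ids, nd$node_id)
    if (length(bad) > 0L)
      stopf("seed node id(s) not in the tree: %s",
            paste(bad, collapse = ", "), class = "cerebropwv_bad_seed")
  }
  unique(ids)
}

tree_graph <- function(tree) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(tree$edges$from),
               to = as.character(tree$edges$to),
               length_mm = tree$edges$length_mm),
    directed = FALSE,
    vertices = data.frame(name = as.character(tree$nodes$node_id)))
}

#' Reduce a tree to its main vascular routes
#'
#' Control-analysis counterpart of manually removing all smaller distal
#' branches: for each endpoint among the deepest fraction of endpoints (by
#' assigned distance), the unique shortest centerline path back to its seed
#' is kept; the union of those paths is returned. False junctions from
#' kissing vessels in the distal tree are eliminated along with the secondary
#' branches.
#'
#' @param tree a `centerline_tree` with distances from [assign_distances()].
#' @param keep_fraction fraction of endpoints (deepest first) whose root
#'   paths are kept; `1` keeps every endpoint (tree unchanged for trees
#'   without secondary structure).
#' @return A rebuilt `centerline_tree` containing only the main routes, with
#'   distances re-assigned from the same seeds.
#' @export
main_routes_only <- function(tree, keep_fraction = 0.25) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (!"distance_mm" %in% names(tree$nodes))
    stopf("assign distances before extracting main routes")
  nd <- tree$nodes
  ends <- nd[nd$node_kind == "endpoint" & nd$reachable, ]
  ends <- ends[!(ends$node_id %in% tree$seeds), ]
  if (nrow(ends) == 0L) return(tree)
  thr <- quantile(ends$distance_mm, probs = 1 - keep_fraction, names = FALSE)
  keep_ends <- ends$node_id[ends$distance_mm >= thr]
  g <- tree_graph(tree)
  keep_ids <- tree$seeds
  for (e in keep_ends) {
    seed <- nd$seed_id[nd$node_id == e]
    sp <- igraph::shortest_paths(g, from = as.character(e),
                                 to = as.character(seed),
                                 weights = igraph::E(g)$length_mm,
                                 output = "vpath")
    keep_ids <- union(keep_ids, as.integer(igraph::as_ids(sp$vpath[[1L]])))
  }
  out <- rebuild_tree(tree, keep_ids)
  # map original seeds to the rebuilt node ids via voxel coordinates
  seeds_ijk <- as.matrix(nd[nd$node_id %in% tree$seeds, c("i", "j", "k")])
  assign_distances(out, seeds_ijk)
}
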