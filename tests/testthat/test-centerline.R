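test_that("skeletonization thins a cylinder to its axis at full length", {
  cyl <- make_cylinder(c(15L, 15L, 48L), c(8L, 8L), 3, c(5L, 44L))
  sk <- skeletonize(cyl)
  w <- which(sk, arr.ind = TRUE)
  expect_true(all(cyl[w]))                       # skeleton within mask
  expect_true(abs(nrow(w) - 40L) <= 4L)          # within 10% of the length
  # one voxel wide: no fully-set 2x2x2 block
  has_block <- FALSE
  for (r in seq_len(nrow(w))) {
    p <- w[r, ]
    if (all(p < dim(sk)) &&
        all(sk[p[1] + 0:1, p[2] + 0:1, p[3] + 0:1])) { has_block <- TRUE; break }
  }
  expect_false(has_block)
})

test_that("skeletonization is idempotent on thin sets and preserves components", {
  dimv <- c(20L, 20L, 20L)
  line <- line_array(cbind(5L, 5L, 3:17), dimv)
  expect_equal(as.logical(skeletonize(line)), as.logical(line))
  two <- make_cylinder(c(15L, 30L, 30L), c(8L, 8L), 2, c(3L, 27L)) |
         make_cylinder(c(15L, 30L, 30L), c(8L, 22L), 2, c(3L, 27L))
  sk <- skeletonize(two)
  tr <- build_tree(sk, 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(tr$edges$from), to = as.character(tr$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(tr$nodes$node_id)))
  expect_equal(igraph::components(g)$no, 2L)
  expect_error(skeletonize(array(FALSE, c(4L, 4L, 4L))),
               class = "cerebropwv_empty_mask")
})

test_that("tree building labels a Y as one junction, three endpoints, three branches", {
  y <- line_array(make_y_lines(), c(20L, 20L, 20L))
  tr <- build_tree(y, 1, prune_spurs = FALSE)
  expect_equal(sum(tr$nodes$node_kind == "junction"), 1L)
  expect_equal(count_junctions(tr), 1L)
  expect_equal(sum(tr$nodes$node_kind == "endpoint"), 3L)
  expect_equal(length(unique(stats::na.omit(tr$nodes$branch_id))), 3L)
})

test_that("tree building handles lines and crossings", {
  line <- line_array(cbind(5L, 5L, 3:17), c(20L, 20L, 20L))
  tr <- build_tree(line, 1)
  expect_equal(sum(tr$nodes$node_kind == "junction"), 0L)
  expect_equal(sum(tr$nodes$node_kind == "endpoint"), 2L)
  expect_equal(length(unique(stats::na.omit(tr$nodes$branch_id))), 1L)
  # X-crossing: two lines sharing one voxel -> center flagged junction, 4 arms
  cross <- rbind(cbind(5:15, 10L, 10L), cbind(10L, 5:15, 10L))
  cross <- cross[!duplicated(cross), ]
  trx <- build_tree(line_array(cross, c(20L, 20L, 20L)), 1, prune_spurs = FALSE)
  ctr <- trx$nodes[trx$nodes$i == 10L & trx$nodes$j == 10L & trx$nodes$k == 10L, ]
  expect_equal(ctr$node_kind, "junction")
  expect_equal(ctr$degree, 4L)
})

test_that("branch decomposition covers every non-junction voxel exactly once", {
  y <- line_array(make_y_lines(), c(20L, 20L, 20L))
  tr <- build_tree(y, 1, prune_spurs = FALSE)
  nonj <- tr$nodes[tr$nodes$node_kind != "junction", ]
  expect_true(all(!is.na(nonj$branch_id)))
  expect_true(all(is.na(tr$nodes$branch_id[tr$nodes$node_kind == "junction"])))
})

test_that("branch selection removes, keeps, and is idempotent", {
  y <- line_array(make_y_lines(), c(20L, 20L, 20L))
  tr <- build_tree(y, 1, prune_spurs = FALSE)
  # remove the branch containing voxel (16,10,16): one diagonal arm
  arm_b <- tr$nodes$branch_id[tr$nodes$i == 16L & tr$nodes$j == 10L & tr$nodes$k == 16L]
  out <- select_branches(tr, arm_b, mode = "remove")
  # the two remaining arms merge: 1 branch, no junctions
  expect_equal(sum(out$nodes$node_kind == "junction"), 0L)
  expect_equal(length(unique(stats::na.omit(out$nodes$branch_id))), 1L)
  # empty removal region: identity
  empty <- array(FALSE, c(20L, 20L, 20L))
  expect_identical(select_branches(tr, empty, mode = "remove"), tr)
  # keep-mode with a region covering exactly one branch
  reg <- array(FALSE, c(20L, 20L, 20L))
  keep_vox <- tr$nodes[!is.na(tr$nodes$branch_id) & tr$nodes$branch_id == arm_b, ]
  reg[cbind(keep_vox$i, keep_vox$j, keep_vox$k)] <- TRUE
  kept <- select_branches(tr, reg, mode = "keep")
  expect_equal(nrow(kept$nodes), nrow(keep_vox))
  # idempotence for a fixed region
  r1 <- select_branches(tr, reg, mode = "remove")
  r2 <- select_branches(r1, reg, mode = "remove")
  expect_equal(r2$nodes[c("i", "j", "k")], r1$nodes[c("i", "j", "k")])
  expect_error(select_branches(tr, unique(stats::na.omit(tr$nodes$branch_id)),
                               mode = "keep") |>
                 select_branches(unique(stats::na.omit(tr$nodes$branch_id)),
                                 mode = "remove"),
               class = "cerebropwv_empty_tree")
})

test_that("tree voxel count is invariant to input voxel enumeration order", {
  coords <- make_y_lines()
  dimv <- c(20L, 20L, 20L)
  t1 <- build_tree(line_array(coords, dimv), 1, prune_spurs = FALSE)
  set.seed(4)
  t2 <- build_tree(line_array(coords[sample.int(nrow(coords)), ], dimv), 1,
                   prune_spurs = FALSE)
  expect_equal(nrow(t1$nodes), nrow(t2$nodes))
  expect_equal(t1$nodes[c("i", "j", "k")], t2$nodes[c("i", "j", "k")])
})
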