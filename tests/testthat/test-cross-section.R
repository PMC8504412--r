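test_that("local direction comes from the two branch neighbors, normalized", {
  # collinear voxels along z at 0.69 mm spacing
  line <- line_array(cbind(5L, 5L, 3:10), c(12L, 12L, 12L))
  tr <- build_tree(line, 0.69)
  mid <- tr$nodes$node_id[tr$nodes$k == 6L]
  expect_equal(local_direction(tr, mid), c(0, 0, 1))
  # diagonal: predecessor (0,0,0), successor (1,1,0) in voxel units
  diagc <- cbind(1:3, 1:3, 1L)
  trd <- build_tree(line_array(diagc, c(5L, 5L, 5L)), 1, prune_spurs = FALSE)
  mid <- trd$nodes$node_id[trd$nodes$i == 2L]
  expect_equal(local_direction(trd, mid), c(1, 1, 0) / sqrt(2))
  # endpoints have no direction
  endp <- trd$nodes$node_id[trd$nodes$node_kind == "endpoint"][1L]
  expect_null(local_direction(trd, endp))
})

test_that("plane extraction is exact on constant and axis-aligned volumes", {
  vol <- structure(array(7, c(11L, 11L, 11L)), voxel_size = c(1, 1, 1))
  pl <- extract_plane(vol, center_mm = c(5, 5, 5), direction = c(0, 0, 1),
                      half_width_mm = 2, upsample = 2L)
  expect_true(all(abs(pl - 7) < 1e-12))
  expect_equal(attr(pl, "pitch_mm"), 0.5)
  # axis-aligned: plane samples reduce to bilinear interpolation in the slice
  set.seed(9)
  vol2 <- structure(array(runif(11^3), c(11L, 11L, 11L)), voxel_size = c(1, 1, 1))
  pl2 <- extract_plane(vol2, c(5, 5, 5), c(0, 0, 1), half_width_mm = 2, upsample = 2L)
  # grid-aligned samples hit voxel values exactly; the plane axes are
  # (0,1,0) and (-1,0,0) for direction (0,0,1)
  e1 <- attr(pl2, "e1"); e2 <- attr(pl2, "e2")
  s <- seq(-2, 2, by = 0.5)
  for (a in c(1L, 5L, 9L)) for (b in c(1L, 5L, 9L)) {
    p_mm <- c(5, 5, 5) + s[a] * e1 + s[b] * e2
    if (all(p_mm == round(p_mm))) {
      expect_equal(pl2[a, b], vol2[p_mm[1] + 1, p_mm[2] + 1, p_mm[3] + 1])
    }
  }
  # midpoint samples are averages of their two grid neighbors (bilinear)
  p_mid <- c(5, 5, 5) + 0.5 * e1
  expect_equal(pl2[which(s == 0.5), which(s == 0)],
               (vol2[5 + e1[1] * 0 + 1, 5 + e1[2] * 0 + 1, 6] +
                vol2[5 + e1[1] + 1, 5 + e1[2] + 1, 6]) / 2,
               tolerance = 1e-12)
  expect_error(extract_plane(vol, c(50, 5, 5), c(0, 0, 1)), "outside")
})

test_that("a perpendicular plane through a cylinder yields a round disk", {
  cyl_cd <- make_cylinder(c(25L, 25L, 40L), c(13L, 13L), 4, c(1L, 40L),
                          value = 10)
  cyl_cd <- structure(cyl_cd, voxel_size = c(1, 1, 1))
  pl <- extract_plane(cyl_cd, c(12, 12, 20), c(0, 0, 1), half_width_mm = 8)
  roi <- segment_roi(pl, search_radius_mm = 3)
  expect_false(is.null(roi))
  # eccentricity from second moments of the ROI
  px <- which(roi$mask, arr.ind = TRUE)
  mu <- colMeans(px)
  cc <- stats::cov(px)
  ev <- eigen(cc, symmetric = TRUE)$values
  ecc <- sqrt(1 - min(ev) / max(ev))
  expect_lt(ecc, 0.2)
})

test_that("ROI segmentation applies the 50% local-peak rule with connectivity", {
  mk_plane <- function(m, pitch = 0.5)
    structure(m, pitch_mm = pitch, e1 = c(1, 0, 0), e2 = c(0, 1, 0),
              center_mm = c(0, 0, 0), direction = c(0, 0, 1))
  n <- 21L; ctr <- 11L
  rr <- (row(matrix(0, n, n)) - ctr); cc <- (col(matrix(0, n, n)) - ctr)
  disk <- (rr^2 + cc^2) <= (2 / 0.5)^2     # 2 mm radius at 0.5 mm pitch
  m <- matrix(0, n, n); m[disk] <- 10
  roi <- segment_roi(mk_plane(m))
  expect_equal(roi$mask, disk)
  expect_equal(roi$roi_area_mm2, sum(disk) * 0.25)
  # a second distant blob must not join the ROI
  m2 <- m; m2[1:3, 1:3] <- 10
  roi2 <- segment_roi(mk_plane(m2))
  expect_equal(roi2$mask, disk)
  # Gaussian vessel profile: mask radius ~ FWHM/2 = sigma * sqrt(2 log 2)
  sigma_mm <- 1.2
  g <- 10 * exp(-((rr * 0.5)^2 + (cc * 0.5)^2) / (2 * sigma_mm^2))
  roig <- segment_roi(mk_plane(g))
  r_eff <- sqrt(roig$roi_area_mm2 / pi)
  expect_equal(r_eff, sigma_mm * sqrt(2 * log(2)), tolerance = 0.15)
  # all-zero plane: no peak, cross-section discarded
  expect_null(segment_roi(mk_plane(matrix(0, n, n))))
})

test_that("ROI waveforms project the mean velocity onto the vessel direction", {
  u <- c(5, 10, 20, 15, 8)
  flow <- make_uniform_flow(u = u, axis = 3L)
  vol <- structure(array(1, c(12L, 12L, 12L)), voxel_size = c(1, 1, 1))
  pl <- extract_plane(vol, c(5, 5, 5), c(0, 0, 1), half_width_mm = 2)
  roi <- matrix(TRUE, nrow(pl), ncol(pl))
  expect_equal(roi_waveform(flow, pl, roi), u, tolerance = 1e-12)
  # flow orthogonal to the direction: zero waveform
  flow_x <- make_uniform_flow(u = u, axis = 1L)
  expect_equal(roi_waveform(flow_x, pl, roi), rep(0, 5), tolerance = 1e-12)
})

test_that("parabolic profiles average to the mean velocity and the result is
           basis-invariant", {
  # vz = 2*ubar*(1 - (rho/R)^2) inside a radius-4 tube, zero outside
  dimv <- c(25L, 25L, 16L); R <- 4; ubar <- 10
  prof <- array(0, dimv)
  for (x in 1:25) for (y in 1:25) {
    rho2 <- (x - 13)^2 + (y - 13)^2
    if (rho2 <= R^2) prof[x, y, ] <- 2 * ubar * (1 - rho2 / R^2)
  }
  M <- 2L
  vz <- array(prof, c(dimv, M))
  zero <- array(0, c(dimv, M))
  flow <- flow_volume(array(1, c(dimv, M)), zero, zero, vz,
                      venc = 110, voxel_size = 1, period = 1)
  pl <- extract_plane(structure(prof, voxel_size = c(1, 1, 1)),
                      c(12, 12, 8), c(0, 0, 1), half_width_mm = 6)
  # ROI: the exact lumen disk in plane pixels
  n <- nrow(pl); ctr <- (n + 1) / 2
  rr <- (row(pl) - ctr) * attr(pl, "pitch_mm")
  cc <- (col(pl) - ctr) * attr(pl, "pitch_mm")
  roi <- (rr^2 + cc^2) <= R^2
  wf <- roi_waveform(flow, pl, roi)
  expect_equal(wf[1L], ubar, tolerance = 0.05 * ubar)
  # rotating the in-plane basis must not change the waveform
  th <- pi / 6
  e1 <- attr(pl, "e1"); e2 <- attr(pl, "e2")
  pl_rot <- pl
  attr(pl_rot, "e1") <- cos(th) * e1 + sin(th) * e2
  attr(pl_rot, "e2") <- -sin(th) * e1 + cos(th) * e2
  wf_rot <- roi_waveform(flow, pl_rot, roi)
  expect_equal(wf_rot, wf, tolerance = 0.01)
})

test_that("waveform normalization demeans, unit-scales, and rejects flat input", {
  nz <- normalize_waveform(c(0, 2))
  expect_equal(nz$waveform, c(-1, 1))
  expect_equal(nz$scaling, 1)
  # affine invariance: c * x + d normalizes to the same curve
  set.seed(2)
  x <- rnorm(20)
  expect_equal(normalize_waveform(3.7 * x + 11)$waveform,
               normalize_waveform(x)$waveform)
  expect_null(normalize_waveform(rep(4, 20)))
  # emitted waveforms have mean 0 and population SD 1
  out <- normalize_waveform(runif(20, -3, 9))$waveform
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out^2)), 1, tolerance = 1e-9)
})

test_that("cross-section weights follow area / scaling^2", {
  expect_equal(cross_section_weight(10, 0.5), 40)
  expect_equal(cross_section_weight(10, 1), 10)
  expect_equal(cross_section_weight(20, 0.7), 2 * cross_section_weight(10, 0.7))
})
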