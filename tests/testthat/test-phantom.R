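# a small, fast tube tree for imaging-phantom tests
small_y_tree <- function() {
  tibble::tibble(
    sx = c(0, 0, 0), sy = c(0, 0, 0), sz = c(5, 30, 30),
    ex = c(0, 8, -8), ey = c(0, 0, 0), ez = c(30, 42, 42),
    radius_mm = 1.5, parent = c(0L, 1L, 1L))
}

test_that("template waveforms behave as parametrized", {
  spec <- phantom_spec(waveform = list(baseline = 10, amplitude = 0,
                                       peak_time = 0.2, width = 0.06))
  expect_equal(make_template_waveform(spec), rep(10, 20))
  spec2 <- phantom_spec(waveform = list(baseline = 10, amplitude = 60,
                                        peak_time = 0.3, width = 0.06))
  tt <- seq(0, spec2$period, length.out = 2000L)
  f <- cerebropwv:::template_fun(spec2)
  expect_equal(tt[which.max(f(tt))], 0.3, tolerance = 1e-3)
  # knot-mode template evaluated at the knots equals the knot vector
  spec3 <- phantom_spec(mode = "knot")
  fk <- cerebropwv:::template_fun(spec3)
  expect_equal(fk(spec3$frame_times), make_template_waveform(spec3))
})

test_that("waveform sets are model-consistent, delayed, and reproducible", {
  spec <- phantom_spec(true_pwv = 10, mode = "knot", seed = 21)
  sim <- simulate_waveform_set(spec, N = 80, noise_sd = 0, normalize = FALSE)
  f <- pwv_fit(sim$records)
  expect_equal(f$pwv, 10, tolerance = 1e-3)
  # forcing zero delays makes all waveforms identical before noise
  spec_inf <- phantom_spec(true_pwv = 1e9, mode = "knot", seed = 21)
  sim0 <- simulate_waveform_set(spec_inf, N = 10, noise_sd = 0, normalize = FALSE)
  vm <- waveform_matrix(sim0$records)
  expect_true(all(abs(sweep(vm, 2L, vm[1L, ])) < 1e-6))
  # fixed seed: identical output across runs
  a <- simulate_waveform_set(spec, N = 40, noise_sd = 0.3, seed = 99)
  b <- simulate_waveform_set(spec, N = 40, noise_sd = 0.3, seed = 99)
  expect_identical(a$records, b$records)
  expect_warning(simulate_waveform_set(spec, N = 10,
                                       distance_range = c(100, 100)),
                 "unidentifiable")
})

test_that("normalized records carry unit-SD waveforms and area weights", {
  spec <- phantom_spec(true_pwv = 8, mode = "knot", seed = 5)
  sim <- simulate_waveform_set(spec, N = 50, noise_sd = 0.3, normalize = TRUE)
  vm <- waveform_matrix(sim$records)
  expect_true(all(abs(rowMeans(vm)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(vm^2)) - 1) < 1e-9))
  expect_equal(sim$records$weight,
               sim$records$area_mm2 / sim$records$scaling^2)
})

test_that("the imaging phantom rasterizes tubes with delayed plug flow", {
  spec <- phantom_spec(true_pwv = 10, mode = "analytic", noise_sd = 0,
                       tree = small_y_tree(), seed = 1)
  ph <- simulate_flow_volume(spec)
  flow <- ph$flow
  # background voxels: zero velocity, near-zero CD
  bg <- !ph$truth$mask
  expect_equal(max(abs(flow$vz[, , , 1][bg])), 0)
  cd <- compute_cd(flow)
  expect_lt(max(cd[bg]) / max(cd), 0.05)
  # lumen is bright in CD
  expect_gt(min(cd[ph$truth$mask & cd > 0]), 0)
  # a Y tree yields one topological junction
  mask <- binarize_global(vesselness_filter(cd))
  tr <- build_tree(skeletonize(mask), flow$voxel_size)
  expect_equal(count_junctions(tr), 1L)
  # velocities beyond venc are refused
  spec_bad <- phantom_spec(waveform = list(baseline = 10, amplitude = 120,
                                           peak_time = 0.2, width = 0.06),
                           tree = small_y_tree())
  expect_error(simulate_flow_volume(spec_bad),
               class = "cerebropwv_invalid_parameter")
})

test_that("extracted waveforms match the injected template within tolerance", {
  # straight tube along z; compare the raw extracted waveform at depth
  tube <- tibble::tibble(sx = 0, sy = 0, sz = 5, ex = 0, ey = 0, ez = 45,
                         radius_mm = 2, parent = 0L)
  spec <- phantom_spec(true_pwv = 10, mode = "analytic", noise_sd = 0,
                       tree = tube, seed = 2)
  ph <- simulate_flow_volume(spec)
  flow <- ph$flow
  cd <- compute_cd(flow)
  # centerline voxel mid-tube: physical coordinates of the axis
  ctr_vox <- round(ph$truth$root_mm / flow$voxel_size) + 1L
  mid <- c(ctr_vox[1L], ctr_vox[2L], ctr_vox[3L] + 29L)
  depth <- ph$truth$depth_mm[mid[1L], mid[2L], mid[3L]]
  ctr_mm <- (mid - 1L) * flow$voxel_size
  pl <- extract_plane(cd, ctr_mm, c(0, 0, 1), half_width_mm = 5,
                      voxel_size = flow$voxel_size)
  # interior ROI (one voxel inside the lumen) isolates interpolation error
  # from boundary partial-volume, which normalization absorbs downstream
  n <- nrow(pl); ctrpx <- (n + 1) / 2
  rr_mm <- (row(pl) - ctrpx) * attr(pl, "pitch_mm")
  cc_mm <- (col(pl) - ctrpx) * attr(pl, "pitch_mm")
  # all 8 trilinear support voxels of each sample must lie in the lumen:
  # radius <= tube radius - voxel diagonal - axis offset
  roi_in <- (rr_mm^2 + cc_mm^2) <= 0.75^2
  raw <- roi_waveform(flow, pl, roi_in)
  injected <- cerebropwv:::template_fun(spec)(
    spec$frame_times - depth / 1000 / spec$true_pwv)
  expect_lt(max(abs(raw - injected)), 0.02 * diff(range(injected)))
  # emitted records all have mean-0 / SD-1 waveforms
  tr <- build_tree(skeletonize(binarize_global(vesselness_filter(cd))),
                   flow$voxel_size)
  root <- ph$truth$root_mm
  near <- which.min((tr$nodes$x - root[1L])^2 + (tr$nodes$y - root[2L])^2 +
                      (tr$nodes$z - root[3L])^2)
  tr <- assign_distances(tr, as.matrix(tr$nodes[near, c("i", "j", "k")]))
  rec <- extract_cross_sections(flow, cd, tr)
  vm <- waveform_matrix(rec)
  expect_true(all(abs(rowMeans(vm)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(vm^2)) - 1) < 1e-9))
  expect_true(all(rec$weight > 0))
})
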