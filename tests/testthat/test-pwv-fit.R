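# knot-mode records drawn exactly from the estimator's model
exact_set <- function(pwv = 10, N = 60, seed = 1, noise_sd = 0,
                      distance_range = c(50, 300)) {
  spec <- phantom_spec(true_pwv = pwv, mode = "knot", seed = seed)
  simulate_waveform_set(spec, N = N, distance_range = distance_range,
                        noise_sd = noise_sd, normalize = noise_sd > 0)
}

test_that("periodic linear interpolation hits knots, midpoints, and wraps", {
  tt <- (0:19) * 0.95 / 20
  V <- c(0, 2, seq(1, 0.5, length.out = 18))
  m <- waveform_model(V, tt, 0.95)
  expect_equal(interp_waveform(m, tt), V)
  expect_equal(interp_waveform(m, (tt[1] + tt[2]) / 2), 1)
  expect_equal(interp_waveform(m, tt[1] - 0.95), V[1])
  expect_equal(interp_waveform(m, tt[5] + 3 * 0.95), V[5])
  # between t_M and t_1 + T the segment joins V_M back to V_1
  expect_equal(interp_waveform(m, tt[20] + 0.95 / 40),
               (V[20] + V[1]) / 2)
})

test_that("the objective is zero on self-consistent data and matches a hand case", {
  sim <- exact_set(pwv = 10, N = 30)
  expect_lt(pwv_objective(sim$records, 10, sim$truth$V), 1e-20)
  # all-zero weights make the objective vanish for any pwv
  rec0 <- sim$records
  rec0$weight <- 0
  expect_equal(pwv_objective(rec0, 3.3, sim$truth$V), 0)
  # 2-frame hand computation: V=(0,1), t=(0,0.5), T=1, r/pwv=0.5
  # predicted (Vtilde(-0.5), Vtilde(0)) = (1, 0); data (0, 1); W=1 -> 2
  rec <- tibble::tibble(cs_id = 1L, distance_mm = 500, weight = 1,
                        v1 = 0, v2 = 1)
  expect_equal(pwv_objective(rec, 1, c(0, 1), frame_times = c(0, 0.5),
                             period = 1), 2)
  expect_error(pwv_objective(rec, -2, c(0, 1), frame_times = c(0, 0.5),
                             period = 1),
               class = "cerebropwv_invalid_parameter")
})

test_that("objective scales exactly with global weight rescaling; argmin unmoved", {
  sim <- exact_set(pwv = 9, N = 120, seed = 3, noise_sd = 0.3)
  obj1 <- pwv_objective(sim$records, 9, sim$truth$V)
  rec_scaled <- sim$records
  rec_scaled$weight <- rec_scaled$weight * 137.5
  obj2 <- pwv_objective(rec_scaled, 9, sim$truth$V)
  expect_lt(abs(obj2 / 137.5 - obj1) / obj1, 1e-12)
  f1 <- pwv_fit(sim$records)
  f2 <- pwv_fit(rec_scaled)
  expect_equal(f2$pwv, f1$pwv, tolerance = 1e-6)
})

test_that("noise-free model-consistent data is recovered exactly and in order", {
  sim <- exact_set(pwv = 10, N = 200, seed = 5)
  f <- pwv_fit(sim$records)
  expect_true(f$converged)
  expect_lt(abs(f$pwv - 10) / 10, 0.001)
  expect_lt(pwv_objective(sim$records, 10, sim$truth$V), 1e-12)
  f8 <- pwv_fit(exact_set(pwv = 8, N = 120, seed = 6)$records)
  f12 <- pwv_fit(exact_set(pwv = 12, N = 120, seed = 6)$records)
  expect_lt(f8$pwv, f12$pwv)
  expect_equal(f8$pwv, 8, tolerance = 0.01)
  expect_equal(f12$pwv, 12, tolerance = 0.01)
})

test_that("a cyclic time shift of every waveform is absorbed into the waveform", {
  sim <- exact_set(pwv = 10, N = 150, seed = 7, noise_sd = 0.3)
  f0 <- pwv_fit(sim$records)
  shifted <- sim$records
  vm <- waveform_matrix(shifted)
  vm_shift <- vm[, c(4:20, 1:3)]            # roll by 3 frames, periodic
  shifted[, paste0("v", 1:20)] <- as.data.frame(vm_shift)
  f1 <- pwv_fit(shifted, frame_times = attr(sim$records, "frame_times"),
                period = attr(sim$records, "period"))
  expect_equal(f1$pwv, f0$pwv, tolerance = 0.01)
})

test_that("delay consistency: estimated pwv tracks 1/slowness", {
  for (s in c(0.05, 0.1, 0.2)) {
    sim <- exact_set(pwv = 1 / s, N = 150, seed = round(1000 * s))
    f <- pwv_fit(sim$records)
    expect_equal(f$pwv, 1 / s, tolerance = 0.01)
  }
})

test_that("the profiled grid oracle pins the optimum and agrees with fit()", {
  sim <- exact_set(pwv = 10, N = 120, seed = 8)
  orc <- profile_fit_oracle(sim$records, pwv_grid = seq(6, 14, by = 0.1))
  expect_equal(orc$best_pwv, 10)
  obj_true <- orc$profile$objective[orc$profile$pwv == 10]
  expect_true(all(orc$profile$objective >= obj_true - 1e-10))
  # noisy fixture: joint fit lands within one grid step of the oracle argmin
  simn <- exact_set(pwv = 10, N = 200, seed = 9, noise_sd = 0.3)
  f <- pwv_fit(simn$records)
  orcn <- profile_fit_oracle(simn$records, pwv_grid = seq(4, 40, by = 0.1))
  expect_lte(abs(f$pwv - orcn$best_pwv), 0.1 + 1e-9)
})

test_that("initialization does not alter a well-posed fit", {
  sim <- exact_set(pwv = 10, N = 200, seed = 10, noise_sd = 0.3)
  f0 <- pwv_fit(sim$records)
  f40 <- pwv_fit(sim$records, init_pwv = 40)
  fV0 <- pwv_fit(sim$records, init_V = rep(0, 20))
  expect_lt(abs(f40$pwv - f0$pwv) / f0$pwv, 0.005)
  expect_lt(abs(fV0$pwv - f0$pwv) / f0$pwv, 0.005)
})

test_that("degenerate geometry and input are rejected", {
  sim <- exact_set(pwv = 10, N = 30, seed = 11)
  rec <- sim$records
  rec$distance_mm <- 100
  expect_error(pwv_fit(rec, frame_times = attr(sim$records, "frame_times"),
                       period = attr(sim$records, "period")),
               class = "cerebropwv_unidentifiable")
  expect_error(pwv_fit(sim$records[1L, ],
                       frame_times = attr(sim$records, "frame_times"),
                       period = attr(sim$records, "period")),
               "at least 2")
})

test_that("split halves agree exactly on clean data and on duplicated records", {
  sim <- exact_set(pwv = 10, N = 100, seed = 12)
  sh <- split_half_consistency(sim$records)
  expect_equal(sh$pwv_odd, 10, tolerance = 1e-3)
  expect_equal(sh$pwv_even, 10, tolerance = 1e-3)
  # duplicating every record makes the halves identical
  simn <- exact_set(pwv = 9, N = 50, seed = 13, noise_sd = 0.3)
  dup <- dplyr::bind_rows(simn$records, simn$records)
  attr(dup, "frame_times") <- attr(simn$records, "frame_times")
  attr(dup, "period") <- attr(simn$records, "period")
  dup <- dup[order(dup$distance_mm), ]
  attr(dup, "frame_times") <- attr(simn$records, "frame_times")
  attr(dup, "period") <- attr(simn$records, "period")
  shd <- split_half_consistency(dup)
  expect_equal(shd$pwv_odd, shd$pwv_even, tolerance = 1e-6)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- exact_set(pwv = 10, N = 60, seed = 14)
  f <- pwv_fit(sim$records)
  td <- tidy(f)
  expect_equal(td$term[1], "pwv")
  expect_equal(nrow(td), 21L)
  gl <- glance(f)
  expect_equal(gl$pwv, f$pwv)
  expect_true(gl$converged)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
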