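#' Digital flow phantom specification
#'
#' Parameters of the synthetic ground-truth generator: a branching tube tree
#' carrying a pulsatile plug-flow waveform that propagates from the root at
#' the true PWV, imaged at the acquisition geometry of a cardiac-gated 4D
#' flow protocol (0.69 mm isotropic voxels, 20 frames per cardiac cycle,
#' venc 110 cm/s by default).
#'
#' @param true_pwv ground-truth pulse wave velocity, m/s.
#' @param M number of cardiac frames.
#' @param period cardiac period, s (0.95 s corresponds to ~63 BPM).
#' @param venc velocity-encoding limit, cm/s.
#' @param voxel_size voxel size, mm (scalar isotropic or 3-vector).
#' @param noise_sd additive Gaussian velocity noise SD. For the imaging
#'   phantom this is in cm/s; for tabular waveform sets it is on the scale of
#'   the unit-SD normalized template.
#' @param waveform template shape parameters: `baseline` and `amplitude` in
#'   cm/s, `peak_time` (s) of the systolic peak, `width` (s) of its Gaussian
#'   envelope.
#' @param mode `"analytic"` (smooth Gaussian-peak template evaluated exactly)
#'   or `"knot"` (template defined only at the frame-time knots and linearly
#'   interpolated with periodic wraparound — the estimator's own model, which
#'   enables exact-recovery tests).
#' @param tree tube-tree geometry for [simulate_flow_volume()]; a tibble of
#'   segments as produced by [phantom_tree_y()].
#' @param seed RNG seed recorded in outputs; `NULL` leaves the RNG state
#'   untouched.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_pwv = 10, M = 20L, period = 0.95, venc = 110,
                         voxel_size = 0.69, noise_sd = 0,
                         waveform = list(baseline = 10, amplitude = 60,
                                         peak_time = 0.2, width = 0.06),
                         mode = c("analytic", "knot"),
                         tree = phantom_tree_y(), seed = NULL) {
  mode <- match.arg(mode)
  if (true_pwv <= 0) stopf("`true_pwv` must be positive")
  if (noise_sd < 0) stopf("`noise_sd` must be non-negative")
  structure(list(true_pwv = true_pwv, M = as.integer(M), period = period,
                 venc = venc, voxel_size = vec3(voxel_size),
                 noise_sd = noise_sd, waveform = waveform, mode = mode,
                 tree = tree, seed = seed,
                 frame_times = frame_times_uniform(M, period)),
            class = "phantom_spec")
}

#' Template waveform at the frame-time knots
#'
#' Deterministic single-systolic-peak waveform: a baseline plus a Gaussian
#' peak (circular distance to the peak time, so the shape is periodic), with
#' diastolic decay back to baseline. Evaluated at the frame times.
#'
#' @param spec a [phantom_spec()].
#' @return Numeric M-vector of template values (cm/s).
#' @export
make_template_waveform <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  template_fun(spec)(spec$frame_times)
}

# the template as a function of continuous time
template_fun <- function(spec) {
  wf <- spec$waveform
  Tp <- spec$period
  analytic <- function(t) {
    dt <- (t - wf$peak_time) %% Tp
    dt <- pmin(dt, Tp - dt)            # circular distance to the peak
    wf$baseline + wf$amplitude * exp(-0.5 * (dt / wf$width)^2)
  }
  if (spec$mode == "analytic") return(analytic)
  knots <- analytic(spec$frame_times)
  model <- waveform_model(knots, spec$frame_times, Tp)
  function(t) interp_waveform(model, t)
}

#' Simulate a tabular cross-section waveform set from the estimator's model
#'
#' Draws cross-section distances, samples an identical but phase-shifted
#' copy of the template waveform at each position (delay `r_i / PWV`), adds
#' Gaussian noise, assigns ROI areas (decreasing with depth, mimicking distal
#' narrowing), and applies the same normalization and weighting as the
#' imaging cross-section extraction. With `normalize = FALSE` the records are
#' drawn exactly from the estimator's model (template knots pre-normalized to
#' mean 0 / SD 1, `scaling = 1`, weight = area), which together with
#' `mode = "knot"` makes noise-free recovery exact.
#'
#' @param spec a [phantom_spec()]; its `mode` selects the template and its
#'   `noise_sd` (unit-SD template scale) the noise level unless overridden.
#' @param N number of cross-sections.
#' @param distance_range range of vascular depths r, mm.
#' @param noise_sd override of `spec$noise_sd`.
#' @param normalize apply per-cross-section demean/SD-normalization (the
#'   realistic path) or emit model-consistent records directly.
#' @param damping_length_mm e-folding length of distal amplitude damping;
#'   `Inf` (default) disables damping.
#' @param area_fun function of the distance vector returning ROI areas in
#'   mm^2; the default tapers the lumen radius linearly from 2.5 mm at the
#'   proximal end to 0.6 mm at the distal end.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return List of class `phantom_set`: `records` (tibble as in
#'   [extract_cross_sections()], with `frame_times`/`period` attributes),
#'   `truth` (list: `pwv`, `V` — the normalized template knots, `template`),
#'   `frame_times`, `period`, `spec`.
#' @export
simulate_waveform_set <- function(spec, N = 200L, distance_range = c(50, 300),
                                  noise_sd = NULL, normalize = TRUE,
                                  damping_length_mm = Inf, area_fun = NULL,
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (N < 2L) stopf("`N` must be at least 2")
  noise_sd <- noise_sd %||% spec$noise_sd
  if (!is.null(seed)) set.seed(seed)
  if (diff(range(distance_range)) == 0)
    warnf("degenerate `distance_range`: all distances equal, PWV unidentifiable")
  tfun <- template_fun(spec)
  # normalize the template to mean 0 / SD 1 at the knots so that noise_sd is
  # on the unit-SD waveform scale
  knots <- tfun(spec$frame_times)
  mu <- mean(knots)
  sg <- sd_pop(knots)
  if (sg == 0) sg <- 1
  Vstar <- (knots - mu) / sg
  nf <- function(t) (tfun(t) - mu) / sg
  r <- sort(runif(N, distance_range[1L], distance_range[2L]))
  d <- (r / 1000) / spec$true_pwv
  tj <- spec$frame_times
  M <- spec$M
  amp <- if (is.finite(damping_length_mm)) exp(-r / damping_length_mm) else rep(1, N)
  area_fun <- area_fun %||% function(r) {
    rng <- range(r)
    frac <- if (diff(rng) > 0) (r - rng[1L]) / diff(rng) else rep(0, length(r))
    radius <- 2.5 - (2.5 - 0.6) * frac
    pi * radius^2
  }
  area <- area_fun(r)
  raw <- matrix(0, N, M)
  for (i in seq_len(N)) raw[i, ] <- amp[i] * nf(tj - d[i])
  if (noise_sd > 0) raw <- raw + matrix(rnorm(N * M, sd = noise_sd), N, M)
  if (normalize) {
    scaling <- numeric(N)
    wave <- matrix(0, N, M)
    keep <- rep(TRUE, N)
    for (i in seq_len(N)) {
      nz <- normalize_waveform(raw[i, ])
      if (is.null(nz)) { keep[i] <- FALSE; next }
      wave[i, ] <- nz$waveform
      scaling[i] <- nz$scaling
    }
    r <- r[keep]; area <- area[keep]; wave <- wave[keep, , drop = FALSE]
    scaling <- scaling[keep]
    weight <- area / scaling^2
  } else {
    wave <- raw
    scaling <- rep(1, N)
    weight <- area
  }
  recs <- tibble(cs_id = seq_along(r), node_id = NA_integer_,
                 branch_id = NA_integer_, distance_mm = r,
                 area_mm2 = area, scaling = scaling, weight = weight)
  wm <- wave
  colnames(wm) <- paste0("v", seq_len(M))
  recs <- dplyr::bind_cols(recs, as_tibble(wm))
  attr(recs, "frame_times") <- tj
  attr(recs, "period") <- spec$period
  structure(list(records = recs,
                 truth = list(pwv = spec$true_pwv, V = Vstar,
                              template = knots, seed = seed),
                 frame_times = tj, period = spec$period, spec = spec),
            class = "phantom_set")
}

#' Default Y-shaped tube tree
#'
#' A serpentine trunk (three parallel vertical runs joined by short
#' horizontal links, 15 mm apart so neighboring tubes never touch) followed
#' by a symmetric bifurcation, reaching ~300 mm of vascular path depth
#' inside a compact field of view.
#'
#' @param radius_mm tube radius in mm.
#' @return Tibble of straight segments with columns `sx, sy, sz, ex, ey, ez`
#'   (segment start/end in mm), `radius_mm`, and `parent` (0 for the root).
#'   Segments connect end-to-start along the `parent` chain.
#' @export
phantom_tree_y <- function(radius_mm = 1.5) {
  tibble(
    sx = c(-22, -22,  -7,  -7,   8,   8,   8),
    sy = c(  0,   0,   0,   0,   0,   0,   0),
    sz = c( 10, 105, 105,  15,  15, 100, 100),
    ex = c(-22,  -7,  -7,   8,   8,   8,   8),
    ey = c(  0,   0,   0,   0,   0,   8,  -8),
    ez = c(105, 105,  15,  15, 100, 115, 115),
    radius_mm = radius_mm,
    parent = c(0L, 1L, 2L, 3L, 4L, 5L, 5L))
}

# cumulative path depth (mm) at the start of every segment
segment_depths <- function(tree) {
  n <- nrow(tree)
  len <- sqrt((tree$ex - tree$sx)^2 + (tree$ey - tree$sy)^2 + (tree$ez - tree$sz)^2)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    depth[i] <- if (p == 0L) 0 else depth[p] + len[p]
  }
  list(start_depth = depth, length = len)
}

#' Simulate a full 4D flow volume of a branching tube phantom
#'
#' Rasterizes the tube tree into a magnitude volume (bright lumen on a dim
#' background) and fills the lumen with plug flow along the local tube axis:
#' at path depth `p` (mm from the root) the speed follows the template
#' delayed by `p / PWV`. Optional Gaussian velocity noise is added
#' everywhere; velocities must stay below venc (aliasing is not modeled).
#' Ground truth (lumen mask, per-voxel path depth, analytic root position)
#' accompanies the volumes for stage-level comparisons.
#'
#' @param spec a [phantom_spec()] whose `tree` defines the geometry.
#' @param margin_mm padding added around the tree bounding box.
#' @param lumen_magnitude,background_magnitude magnitude values inside and
#'   outside the tubes.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return List of class `phantom_flow`: `flow` (a [flow_volume()]), `truth`
#'   (list: `mask`, `depth_mm` array, `root_mm`, `max_depth_mm`, `tree`,
#'   `template`, `pwv`, `seed`).
#' @export
simulate_flow_volume <- function(spec, margin_mm = 6,
                                 lumen_magnitude = 100,
                                 background_magnitude = 2,
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  tree <- spec$tree
  vs <- spec$voxel_size
  sd_info <- segment_depths(tree)
  lo <- c(min(c(tree$sx, tree$ex)), min(c(tree$sy, tree$ey)), min(c(tree$sz, tree$ez))) -
    margin_mm
  hi <- c(max(c(tree$sx, tree$ex)), max(c(tree$sy, tree$ey)), max(c(tree$sz, tree$ez))) +
    margin_mm
  dims <- as.integer(ceiling((hi - lo) / vs)) + 1L
  # per-voxel lumen state
  depth <- array(Inf, dims)
  dirx <- array(0, dims); diry <- array(0, dims); dirz <- array(0, dims)
  ax_mm <- (seq_len(dims[1L]) - 1) * vs[1L] + lo[1L]
  ay_mm <- (seq_len(dims[2L]) - 1) * vs[2L] + lo[2L]
  az_mm <- (seq_len(dims[3L]) - 1) * vs[3L] + lo[3L]
  for (si in seq_len(nrow(tree))) {
    s0 <- c(tree$sx[si], tree$sy[si], tree$sz[si])
    s1 <- c(tree$ex[si], tree$ey[si], tree$ez[si])
    rad <- tree$radius_mm[si]
    L <- sd_info$length[si]
    u <- (s1 - s0) / L
    pad <- rad + max(vs)
    ix <- which(ax_mm >= min(s0[1L], s1[1L]) - pad & ax_mm <= max(s0[1L], s1[1L]) + pad)
    iy <- which(ay_mm >= min(s0[2L], s1[2L]) - pad & ay_mm <= max(s0[2L], s1[2L]) + pad)
    iz <- which(az_mm >= min(s0[3L], s1[3L]) - pad & az_mm <= max(s0[3L], s1[3L]) + pad)
    if (length(ix) == 0L || length(iy) == 0L || length(iz) == 0L) next
    g <- expand.grid(x = ax_mm[ix], y = ay_mm[iy], z = az_mm[iz])
    rel <- cbind(g$x - s0[1L], g$y - s0[2L], g$z - s0[3L])
    tpar <- rel %*% u
    tclip <- pmin(pmax(tpar, 0), L)
    radial2 <- rowSums((rel - tclip %*% t(u))^2)
    inside <- radial2 <= rad^2
    if (!any(inside)) next
    gi <- expand.grid(i = ix, j = iy, k = iz)
    lin <- gi$i + (gi$j - 1L) * dims[1L] + (gi$k - 1L) * dims[1L] * dims[2L]
    lin <- lin[inside]
    dnew <- sd_info$start_depth[si] + tclip[inside]
    better <- dnew < depth[lin]
    lin <- lin[better]
    depth[lin] <- dnew[better]
    dirx[lin] <- u[1L]; diry[lin] <- u[2L]; dirz[lin] <- u[3L]
  }
  mask <- is.finite(depth)
  if (!any(mask)) stopf("tube tree does not intersect the field of view")
  lumen <- which(mask)
  tfun <- template_fun(spec)
  # peak velocity check against venc
  dense_t <- seq(0, spec$period, length.out = 512L)
  vmax <- max(abs(tfun(dense_t))) + 4 * spec$noise_sd
  if (vmax >= spec$venc)
    stopf("requested velocity (%.1f cm/s) reaches venc (%.1f cm/s); aliasing not modeled",
          vmax, spec$venc, class = "cerebropwv_invalid_parameter")
  M <- spec$M
  mag3 <- array(background_magnitude, dims)
  mag3[lumen] <- lumen_magnitude
  magnitude <- array(mag3, c(dims, M))
  vx <- array(0, c(dims, M)); vy <- array(0, c(dims, M)); vz <- array(0, c(dims, M))
  nvox <- prod(dims)
  delay <- (depth[lumen] / 1000) / spec$true_pwv
  for (jf in seq_len(M)) {
    speed <- tfun(spec$frame_times[jf] - delay)
    ofs <- (jf - 1L) * nvox
    vx[ofs + lumen] <- speed * dirx[lumen]
    vy[ofs + lumen] <- speed * diry[lumen]
    vz[ofs + lumen] <- speed * dirz[lumen]
  }
  if (spec$noise_sd > 0) {
    vx <- vx + array(rnorm(length(vx), sd = spec$noise_sd), dim(vx))
    vy <- vy + array(rnorm(length(vy), sd = spec$noise_sd), dim(vy))
    vz <- vz + array(rnorm(length(vz), sd = spec$noise_sd), dim(vz))
  }
  flow <- flow_volume(magnitude, vx, vy, vz, venc = spec$venc,
                      voxel_size = vs, frame_times = spec$frame_times,
                      period = spec$period)
  root_mm <- c(tree$sx[1L], tree$sy[1L], tree$sz[1L]) - lo
  structure(list(
    flow = flow,
    truth = list(mask = mask, depth_mm = depth, origin_mm = lo,
                 root_mm = root_mm,
                 max_depth_mm = max(depth[lumen]),
                 tree = tree, template = make_template_waveform(spec),
                 pwv = spec$true_pwv, seed = seed)),
    class = "phantom_flow")
}
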