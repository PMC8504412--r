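#' Complex-difference angiogram
#'
#' Combines the temporal-mean magnitude and velocity images into a
#' complex-difference (CD) angiogram, `CD = m * sin(theta)` with
#' `theta = pi * ||v|| / venc` truncated to `[0, pi/2]`. Each velocity
#' component is averaged over the cardiac frames first; the speed `||v||` is
#' the norm of the component-wise means, which preserves flow directionality
#' as in standard phase-contrast MRA practice.
#'
#' @param flow a [flow_volume()].
#' @return A 3D array of class `cd_volume` (non-negative where finite) with
#'   attributes `voxel_size`, `venc` and `truncated` (provenance of the
#'   theta truncation).
#' @export
compute_cd <- function(flow) {
  stopifnot(inherits(flow, "flow_volume"))
  if (flow$venc <= 0)
    stopf("`venc` must be positive", class = "cerebropwv_invalid_parameter")
  mbar <- rowMeans(flow$magnitude, dims = 3L)
  vxb <- rowMeans(flow$vx, dims = 3L)
  vyb <- rowMeans(flow$vy, dims = 3L)
  vzb <- rowMeans(flow$vz, dims = 3L)
  speed <- sqrt(vxb^2 + vyb^2 + vzb^2)
  n_nan <- sum(!is.finite(mbar) | !is.finite(speed))
  if (n_nan > 0)
    warnf("%d voxel(s) with non-finite magnitude/velocity propagate as NaN", n_nan)
  theta <- pmin(pi * speed / flow$venc, pi / 2)
  cd <- mbar * sin(theta)
  structure(cd, voxel_size = flow$voxel_size, venc = flow$venc,
            truncated = TRUE, class = c("cd_volume", class(cd)))
}

# 1D Gaussian and Gaussian-derivative correlation kernels (voxel units) with
# exact discrete moment normalization, so derivatives are correct even at
# sub-voxel sigma
gauss_kernels <- function(sigma) {
  h <- max(3L, ceiling(3.5 * sigma))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g0 <- g / sum(g)
  k1 <- x * g
  k1 <- k1 / sum(x * k1)              # first derivative: sum(t * k) = 1
  k2 <- (x^2 - sigma^2) * g
  k2 <- k2 - mean(k2)                 # second derivative: zero DC ...
  k2 <- k2 / (sum(x^2 * k2) / 2)      # ... and sum(t^2 * k) / 2 = 1
  list(g0 = g0, g1 = k1, g2 = k2)
}

#' Multiscale Hessian vesselness filter
#'
#' Enhances bright tubular structures with the tau-parameterized
#' Hessian-eigenvalue vesselness response. At each scale the Hessian is
#' computed by Gaussian-derivative filtering (physical mm units, reflection
#' at the boundary, gamma = 2 scale normalization); eigenvalues are sorted by
#' magnitude and the response uses the regularized largest eigenvalue with
#' cut-off `tau`. The final response is the maximum over scales and lies in
#' `[0, 1]`; voxels failing the bright-tube eigenvalue sign conditions score 0.
#'
#' @param cd a `cd_volume` from [compute_cd()], or any 3D array with a
#'   `voxel_size` attribute (or supplied via `voxel_size`).
#' @param scales_mm positive Gaussian scales in mm to probe.
#' @param tau regularization cut-off in (0, 1]; smaller values respond more
#'   uniformly inside large vessels.
#' @param voxel_size voxel size override in mm.
#' @return 3D array in `[0, 1]` with attributes `scales_mm`, `tau`,
#'   `voxel_size`.
#' @export
vesselness_filter <- function(cd, scales_mm = c(0.5, 1, 1.5, 2), tau = 1,
                              voxel_size = NULL) {
  if (length(scales_mm) == 0L || any(!is.finite(scales_mm)) || any(scales_mm <= 0))
    stopf("`scales_mm` must be non-empty and positive",
          class = "cerebropwv_invalid_parameter")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stopf("`tau` must be a positive scalar", class = "cerebropwv_invalid_parameter")
  voxel_size <- vec3(voxel_size %||% attr(cd, "voxel_size") %||% 1)
  vol <- as.numeric(cd)
  if (any(!is.finite(vol))) stopf("`cd` must be finite for vesselness filtering")
  d <- dim(cd)
  out <- array(0, d)
  for (s in scales_mm) {
    sig_vox <- s / voxel_size
    kx <- gauss_kernels(sig_vox[1L]); ky <- gauss_kernels(sig_vox[2L]); kz <- gauss_kernels(sig_vox[3L])
    conv <- function(a, b, c) cpp_conv3_sep(vol, d, a, b, c)
    # physical second derivatives (divide by voxel size per derivative axis),
    # gamma = 2 normalization multiplies by s^2
    s2 <- s^2
    hxx <- conv(kx$g2, ky$g0, kz$g0) / voxel_size[1L]^2 * s2
    hyy <- conv(kx$g0, ky$g2, kz$g0) / voxel_size[2L]^2 * s2
    hzz <- conv(kx$g0, ky$g0, kz$g2) / voxel_size[3L]^2 * s2
    hxy <- conv(kx$g1, ky$g1, kz$g0) / (voxel_size[1L] * voxel_size[2L]) * s2
    hxz <- conv(kx$g1, ky$g0, kz$g1) / (voxel_size[1L] * voxel_size[3L]) * s2
    hyz <- conv(kx$g0, ky$g1, kz$g1) / (voxel_size[2L] * voxel_size[3L]) * s2
    ev <- cpp_hessian_eigs(hxx, hyy, hzz, hxy, hxz, hyz)
    # bright tubes: lambda2, lambda3 strongly negative; flip signs
    l2 <- -ev$l2
    l3 <- -ev$l3
    mx <- max(l3, 0)
    # guard against floating-point Hessian noise on flat regions
    if (mx <= 1e-9 * max(abs(vol), 1e-300)) next
    lr <- l3
    lr[l3 > 0 & l3 <= tau * mx] <- tau * mx
    lr[l3 <= 0] <- 0
    resp <- numeric(length(l2))
    ok <- l2 > 0 & lr > 0
    capped <- ok & (l2 >= lr / 2)
    resp[capped] <- 1
    mid <- ok & !capped
    resp[mid] <- l2[mid]^2 * (lr[mid] - l2[mid]) * (3 / (l2[mid] + lr[mid]))^3
    out <- pmax(out, array(resp, d))
  }
  structure(out, scales_mm = scales_mm, tau = tau, voxel_size = voxel_size)
}

#' Global-threshold binarization of a filtered angiogram
#'
#' Thresholds a vessel-enhanced volume at a fraction of its global maximum
#' (default 2.5%). Non-finite voxels are excluded from the maximum and never
#' enter the mask.
#'
#' @param filtered 3D array (typically from [vesselness_filter()]).
#' @param fraction threshold as a fraction of the global maximum.
#' @param voxel_size voxel size override in mm.
#' @return Logical 3D array of class `vessel_mask` with attributes
#'   `threshold_fraction` and `voxel_size`.
#' @export
binarize_global <- function(filtered, fraction = 0.025, voxel_size = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0)
    stopf("`fraction` must be a non-negative scalar",
          class = "cerebropwv_invalid_parameter")
  voxel_size <- vec3(voxel_size %||% attr(filtered, "voxel_size") %||% 1)
  mx <- suppressWarnings(max(filtered[is.finite(filtered)]))
  if (!is.finite(mx) || mx <= 0)
    stopf("filtered volume has no positive values; no vessels detectable",
          class = "cerebropwv_empty_mask")
  mask <- !is.na(filtered) & is.finite(filtered) &
    (if (fraction > 0) filtered >= fraction * mx else filtered > 0)
  mask <- array(mask, dim(filtered))
  structure(mask, threshold_fraction = fraction, voxel_size = voxel_size,
            class = c("vessel_mask", class(mask)))
}
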