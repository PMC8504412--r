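#' Cardiac-gated 4D flow acquisition
#'
#' Container for one cardiac-gated 4D flow MRI reconstruction: a magnitude
#' volume and three velocity-component volumes per cardiac time frame, plus
#' the acquisition parameters needed downstream (velocity-encoding limit,
#' voxel size, frame times).
#'
#' @param magnitude 4D array `(x, y, z, frame)` of signal magnitude
#'   (arbitrary units, non-negative).
#' @param vx,vy,vz 4D arrays of the x/y/z velocity components in cm/s, same
#'   dimensions as `magnitude`.
#' @param venc velocity-encoding limit in cm/s (positive scalar).
#' @param voxel_size voxel edge length(s) in mm; scalar (isotropic) or
#'   3-vector.
#' @param frame_times times of the cardiac frames in seconds, strictly
#'   increasing, one per frame. Defaults to a uniform grid
#'   `(j-1) * period / M` when `period` is given instead.
#' @param period cardiac period in seconds; used to build default
#'   `frame_times` and retained for periodic waveform interpolation.
#'
#' @return An object of class `flow_volume`: a list with elements
#'   `magnitude`, `vx`, `vy`, `vz`, `venc`, `voxel_size`, `frame_times`,
#'   `period`, and `M` (number of frames).
#' @export
flow_volume <- function(magnitude, vx, vy, vz, venc, voxel_size,
                        frame_times = NULL, period = NULL) {
  d <- dim(magnitude)
  if (is.null(d) || length(d) != 4L)
    stopf("`magnitude` must be a 4D array (x, y, z, frame)")
  for (nm in c("vx", "vy", "vz")) {
    v <- get(nm)
    if (!identical(dim(v), d))
      stopf("`%s` must share the magnitude grid (%s)", nm,
            paste(d, collapse = "x"))
  }
  if (!is.numeric(venc) || length(venc) != 1L || !is.finite(venc) || venc <= 0)
    stopf("`venc` must be a positive scalar (cm/s)", class = "cerebropwv_invalid_parameter")
  voxel_size <- vec3(voxel_size)
  M <- d[4L]
  if (M < 2L) stopf("need at least 2 cardiac frames, got %d", M)
  if (is.null(frame_times)) {
    if (is.null(period)) stopf("supply `frame_times` or `period`")
    frame_times <- frame_times_uniform(M, period)
  }
  if (length(frame_times) != M)
    stopf("`frame_times` must have one entry per frame (%d)", M)
  if (any(diff(frame_times) <= 0))
    stopf("`frame_times` must be strictly increasing")
  if (is.null(period)) period <- infer_period(frame_times)
  if (period <= frame_times[M] - frame_times[1L])
    stopf("cardiac `period` must exceed the frame time span")
  structure(
    list(magnitude = magnitude, vx = vx, vy = vy, vz = vz,
         venc = venc, voxel_size = voxel_size,
         frame_times = as.numeric(frame_times), period = period, M = M),
    class = "flow_volume")
}

#' @export
print.flow_volume <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<flow_volume> %dx%dx%d voxels, %d frames\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm, venc: %g cm/s, period: %.3f s\n",
              paste(signif(x$voxel_size, 3), collapse = "x"), x$venc, x$period))
  invisible(x)
}

#' Read a 4D flow acquisition from NIfTI files
#'
#' Reads one magnitude and three velocity-component NIfTI volumes (4D, time
#' as the 4th axis) together with a YAML or JSON sidecar holding the
#' acquisition parameters.
#'
#' @param magnitude,vx,vy,vz paths to NIfTI volumes.
#' @param sidecar path to a YAML (`.yaml`/`.yml`) or JSON sidecar with fields
#'   `venc` (cm/s), and either `frame_times` (s) or `period` (s); an optional
#'   `voxel_size` overrides the NIfTI header.
#' @return A [flow_volume()].
#' @export
read_flow_nifti <- function(magnitude, vx, vy, vz, sidecar) {
  for (p in c(magnitude, vx, vy, vz, sidecar))
    if (!file.exists(p)) stopf("input file not found: %s", p)
  meta <- if (grepl("\\.ya?ml$", sidecar)) yaml::read_yaml(sidecar)
          else jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- RNifti::readNifti(magnitude)
  vox <- meta$voxel_size %||% RNifti::pixdim(img)[1:3]
  flow_volume(
    magnitude = unclass(img)[, , , , drop = FALSE],
    vx = unclass(RNifti::readNifti(vx))[, , , , drop = FALSE],
    vy = unclass(RNifti::readNifti(vy))[, , , , drop = FALSE],
    vz = unclass(RNifti::readNifti(vz))[, , , , drop = FALSE],
    venc = meta$venc, voxel_size = vox,
    frame_times = meta$frame_times, period = meta$period)
}

#' Write a 3D volume to NIfTI
#'
#' @param vol 3D array (e.g. an angiogram, filter response, or mask).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel size in mm (scalar or 3-vector); defaults to the
#'   volume's `voxel_size` attribute when present.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = NULL) {
  voxel_size <- vec3(voxel_size %||% attr(vol, "voxel_size") %||% 1)
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
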