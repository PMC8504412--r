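#' Local vessel direction at a centerline voxel
#'
#' Direction estimated from three consecutive centerline voxels centered on
#' the analyzed position: the normalized physical-coordinate difference
#' between the successor and predecessor neighbors. When distances are
#' available the sign is oriented away from the root (increasing distance);
#' otherwise a fixed canonical sign is used (largest-magnitude component
#' positive).
#'
#' @param tree a `centerline_tree`.
#' @param node_id id of an interior branch voxel (exactly two neighbors).
#' @return Unit 3-vector, or `NULL` when the voxel is an endpoint or junction
#'   (no direction; the cross-section is skipped).
#' @export
local_direction <- function(tree, node_id) {
  nd <- tree$nodes
  row <- nd[nd$node_id == node_id, ]
  if (nrow(row) != 1L) stopf("unknown node id %s", node_id)
  if (row$node_kind != "interior") return(NULL)
  e <- tree$edges
  nbr <- c(e$to[e$from == node_id], e$from[e$to == node_id])
  if (length(nbr) != 2L) return(NULL)
  a <- nd[match(nbr[1L], nd$node_id), ]
  b <- nd[match(nbr[2L], nd$node_id), ]
  # orient: predecessor = smaller distance when known, else smaller node id
  have_dist <- "distance_mm" %in% names(nd) &&
    !is.na(a$distance_mm) && !is.na(b$distance_mm)
  ord <- if (have_dist) a$distance_mm <= b$distance_mm else TRUE
  pre <- if (ord) a else b
  suc <- if (ord) b else a
  dir <- unit(c(suc$x - pre$x, suc$y - pre$y, suc$z - pre$z))
  if (!have_dist) {
    # canonical sign when no root orientation exists
    if (dir[which.max(abs(dir))] < 0) dir <- -dir
  }
  dir
}

#' Extract a cross-sectional plane from a volume
#'
#' Resamples a 3D volume on a square grid orthogonal to `direction`, centered
#' at `center_mm`, by trilinear interpolation. The in-plane pixel pitch is
#' `min(voxel_size) / upsample` (factor-two upsampling by default). Pixels
#' falling outside the volume are `NA` (clipped with a warning).
#'
#' @param volume 3D array.
#' @param center_mm plane center in mm (physical coordinates, voxel index
#'   times voxel size).
#' @param direction unit normal of the plane.
#' @param half_width_mm plane half-width in mm.
#' @param upsample in-plane upsampling factor (integer >= 1).
#' @param voxel_size voxel size in mm.
#' @return Numeric matrix with attributes `pitch_mm`, `e1`, `e2`,
#'   `center_mm`, `direction`.
#' @export
extract_plane <- function(volume, center_mm, direction, half_width_mm = 5,
                          upsample = 2L, voxel_size = NULL) {
  voxel_size <- vec3(voxel_size %||% attr(volume, "voxel_size") %||% 1)
  d <- dim(volume)
  cv <- center_mm / voxel_size            # 0-based voxel coordinates
  if (any(cv < 0) || any(cv > d - 1L))
    stopf("plane center lies outside the volume")
  basis <- plane_basis(direction)
  pitch <- min(voxel_size) / upsample
  s <- seq(-half_width_mm, half_width_mm, by = pitch)
  grid <- expand.grid(u = s, v = s)
  pts_mm <- outer(grid$u, basis$e1) + outer(grid$v, basis$e2)
  pts_mm <- sweep(pts_mm, 2L, center_mm, "+")
  pts_vox <- sweep(pts_mm, 2L, voxel_size, "/")
  vals <- cpp_sample_trilinear(as.numeric(volume), d, pts_vox)
  if (anyNA(vals))
    warnf("cross-section plane clipped at the volume boundary (%d px)",
          sum(is.na(vals)))
  m <- matrix(vals, nrow = length(s), ncol = length(s))
  structure(m, pitch_mm = pitch, e1 = basis$e1, e2 = basis$e2,
            center_mm = center_mm, direction = unit(direction))
}

#' Segment the lumen ROI in a CD cross-section
#'
#' Local-threshold lumen segmentation: the peak CD value is located within a
#' search disk around the plane center, pixels at or above
#' `roi_threshold * peak` are kept, and the 8-connected component containing
#' (or nearest to) the center pixel becomes the ROI.
#'
#' @param cd_plane matrix from [extract_plane()] on the CD angiogram.
#' @param roi_threshold threshold as a fraction of the local peak (default
#'   0.5).
#' @param search_radius_mm radius of the peak-search disk around the plane
#'   center, in mm.
#' @return List with `mask` (logical matrix), `roi_area_mm2`, and `peak`, or
#'   `NULL` when no positive peak exists (cross-section discarded).
#' @export
segment_roi <- function(cd_plane, roi_threshold = 0.5, search_radius_mm = 3) {
  pitch <- attr(cd_plane, "pitch_mm") %||% 1
  n <- nrow(cd_plane)
  ctr <- (n + 1) / 2
  rr <- row(cd_plane) - ctr
  cc <- col(cd_plane) - ctr
  dist_px <- sqrt(rr^2 + cc^2)
  search <- dist_px <= search_radius_mm / pitch
  vals <- cd_plane[search]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) return(NULL)
  peak <- max(vals)
  if (peak <= 0) return(NULL)
  mask <- is.finite(cd_plane) & cd_plane >= roi_threshold * peak
  if (!any(mask)) return(NULL)
  lab <- label_components_8(mask)
  ctr_px <- c(round(ctr), round(ctr))
  target <- lab[ctr_px[1L], ctr_px[2L]]
  if (target == 0L) {
    # nearest labeled pixel to the center
    cand <- which(lab > 0L, arr.ind = TRUE)
    dd <- (cand[, 1L] - ctr)^2 + (cand[, 2L] - ctr)^2
    target <- lab[cand[which.min(dd), , drop = FALSE]]
  }
  roi <- lab == target
  list(mask = roi, roi_area_mm2 = sum(roi) * pitch^2, peak = peak)
}

# 8-connected component labeling of a small logical matrix (BFS)
label_components_8 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      pr <- (p - 1L) %% d[1L] + 1L
      pc <- (p - 1L) %/% d[1L] + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        qr <- pr + dr; qc <- pc + dc
        if (qr < 1L || qc < 1L || qr > d[1L] || qc > d[2L]) next
        q <- qr + (qc - 1L) * d[1L]
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Time-resolved through-plane velocity waveform of one ROI
#'
#' For each cardiac frame, the three velocity components are averaged over
#' the ROI pixels (each sampled by the same plane resampling as the CD
#' image), forming a mean velocity vector whose dot product with the vessel
#' direction gives the frame's velocity estimate.
#'
#' @param flow a [flow_volume()].
#' @param plane a plane from [extract_plane()] (supplies the geometry).
#' @param roi logical matrix from [segment_roi()].
#' @param frames optional precomputed per-frame velocity slices from
#'   `velocity_frames()` (internal; avoids repeated 4D copies in bulk
#'   extraction).
#' @return Numeric M-vector of through-plane velocities (cm/s).
#' @export
roi_waveform <- function(flow, plane, roi, frames = NULL) {
  if (!any(roi)) stopf("ROI is empty")
  pitch <- attr(plane, "pitch_mm")
  e1 <- attr(plane, "e1"); e2 <- attr(plane, "e2")
  ctr_mm <- attr(plane, "center_mm")
  dirn <- attr(plane, "direction")
  n <- nrow(plane)
  s <- (seq_len(n) - (n + 1) / 2) * pitch
  px <- which(roi, arr.ind = TRUE)
  pts_mm <- outer(s[px[, 1L]], e1) + outer(s[px[, 2L]], e2)
  pts_mm <- sweep(pts_mm, 2L, ctr_mm, "+")
  pts_vox <- sweep(pts_mm, 2L, flow$voxel_size, "/")
  d3 <- dim(flow$magnitude)[1:3]
  M <- flow$M
  if (is.null(frames)) frames <- velocity_frames(flow)
  out <- numeric(M)
  for (jf in seq_len(M)) {
    mx <- mean(cpp_sample_trilinear(frames$vx[[jf]], d3, pts_vox), na.rm = TRUE)
    my <- mean(cpp_sample_trilinear(frames$vy[[jf]], d3, pts_vox), na.rm = TRUE)
    mz <- mean(cpp_sample_trilinear(frames$vz[[jf]], d3, pts_vox), na.rm = TRUE)
    out[jf] <- sum(c(mx, my, mz) * dirn)
  }
  out
}

# split the 4D velocity arrays into per-frame numeric vectors once
velocity_frames <- function(flow) {
  M <- flow$M
  list(
    vx = lapply(seq_len(M), function(j) as.numeric(flow$vx[, , , j])),
    vy = lapply(seq_len(M), function(j) as.numeric(flow$vy[, , , j])),
    vz = lapply(seq_len(M), function(j) as.numeric(flow$vz[, , , j])))
}

#' Normalize a velocity waveform
#'
#' Removes the temporal mean and scales by the reciprocal of the standard
#' deviation (population SD, divisor M). Flat waveforms (SD = 0) cannot be
#' normalized and are discarded upstream.
#'
#' @param raw numeric waveform.
#' @return List with `waveform` (mean 0, SD 1) and `scaling` (`1 / SD`), or
#'   `NULL` when `SD(raw) == 0`.
#' @export
normalize_waveform <- function(raw) {
  s <- sd_pop(raw)
  if (!is.finite(s) || s == 0) return(NULL)
  scaling <- 1 / s
  list(waveform = (raw - mean(raw)) * scaling, scaling = scaling)
}

#' Cross-section weight
#'
#' Weight proportional to the reciprocal of the measurement variance:
#' `W = area / scaling^2`.
#'
#' @param roi_area_mm2 ROI area in mm^2.
#' @param scaling reciprocal-SD scaling from [normalize_waveform()].
#' @return Positive scalar weight.
#' @export
cross_section_weight <- function(roi_area_mm2, scaling) {
  stopifnot(roi_area_mm2 > 0, scaling > 0)
  roi_area_mm2 / scaling^2
}

#' Extract all cross-section records from a flow acquisition
#'
#' Walks every interior (non-junction) centerline voxel, places a plane
#' perpendicular to the local vessel direction, segments the lumen ROI in the
#' CD cross-section, computes the normalized time-resolved through-plane
#' velocity waveform and its weight, and returns one row per surviving
#' cross-section. Cross-sections at endpoints, at junctions, or within one
#' voxel of a junction are skipped, as are unreachable voxels (when distances
#' are assigned), empty ROIs and flat waveforms; skip reasons are tallied in
#' the `skipped` attribute.
#'
#' @param flow a [flow_volume()].
#' @param cd the CD angiogram from [compute_cd()].
#' @param tree a `centerline_tree`, ideally with distances from
#'   [assign_distances()].
#' @param half_width_mm plane half-width in mm.
#' @param upsample in-plane upsampling factor.
#' @param roi_threshold local ROI threshold as a fraction of the peak.
#' @param search_radius_mm peak-search disk radius in mm.
#' @return A tibble with columns `cs_id`, `node_id`, `branch_id`,
#'   `distance_mm`, `x`, `y`, `z`, `dir_x`, `dir_y`, `dir_z`,
#'   `area_mm2`, `scaling`, `weight`, and waveform columns `v1 ... vM`
#'   (normalized, mean 0 / SD 1). Frame times and period are attached as
#'   attributes `frame_times` and `period`.
#' @export
extract_cross_sections <- function(flow, cd, tree, half_width_mm = 5,
                                   upsample = 2L, roi_threshold = 0.5,
                                   search_radius_mm = 3) {
  stopifnot(inherits(flow, "flow_volume"), inherits(tree, "centerline_tree"))
  nd <- tree$nodes
  have_dist <- "distance_mm" %in% names(nd)
  # voxels adjacent to a junction (1-voxel margin)
  junction_ids <- nd$node_id[nd$node_kind == "junction"]
  near_junction <- unique(c(
    tree$edges$from[tree$edges$to %in% junction_ids],
    tree$edges$to[tree$edges$from %in% junction_ids]))
  skipped <- c(endpoint_or_junction = 0L, near_junction = 0L,
               unreachable = 0L, empty_roi = 0L, flat_waveform = 0L,
               no_direction = 0L)
  rows <- list()
  wavemat <- list()
  csi <- 0L
  frames <- velocity_frames(flow)
  for (q in seq_len(nrow(nd))) {
    node <- nd[q, ]
    if (node$node_kind != "interior" || is.na(node$branch_id)) {
      skipped["endpoint_or_junction"] <- skipped["endpoint_or_junction"] + 1L
      next
    }
    if (node$node_id %in% near_junction) {
      skipped["near_junction"] <- skipped["near_junction"] + 1L
      next
    }
    if (have_dist && !isTRUE(node$reachable)) {
      skipped["unreachable"] <- skipped["unreachable"] + 1L
      next
    }
    dirn <- local_direction(tree, node$node_id)
    if (is.null(dirn)) {
      skipped["no_direction"] <- skipped["no_direction"] + 1L
      next
    }
    ctr <- c(node$x, node$y, node$z)
    plane <- suppressWarnings(
      extract_plane(cd, ctr, dirn, half_width_mm, upsample, flow$voxel_size))
    roi <- segment_roi(plane, roi_threshold, search_radius_mm)
    if (is.null(roi)) {
      skipped["empty_roi"] <- skipped["empty_roi"] + 1L
      next
    }
    raw <- roi_waveform(flow, plane, roi$mask, frames = frames)
    nz <- normalize_waveform(raw)
    if (is.null(nz)) {
      skipped["flat_waveform"] <- skipped["flat_waveform"] + 1L
      next
    }
    csi <- csi + 1L
    rows[[csi]] <- tibble(
      cs_id = csi, node_id = node$node_id, branch_id = node$branch_id,
      distance_mm = if (have_dist) node$distance_mm else NA_real_,
      x = node$x, y = node$y, z = node$z,
      dir_x = dirn[1L], dir_y = dirn[2L], dir_z = dirn[3L],
      area_mm2 = roi$roi_area_mm2, scaling = nz$scaling,
      weight = cross_section_weight(roi$roi_area_mm2, nz$scaling))
    wavemat[[csi]] <- nz$waveform
  }
  if (csi == 0L)
    stopf("no usable cross-sections were extracted",
          class = "cerebropwv_no_cross_sections")
  out <- dplyr::bind_rows(rows)
  wm <- do.call(rbind, wavemat)
  colnames(wm) <- paste0("v", seq_len(ncol(wm)))
  out <- dplyr::bind_cols(out, as_tibble(wm))
  attr(out, "frame_times") <- flow$frame_times
  attr(out, "period") <- flow$period
  attr(out, "skipped") <- skipped
  out
}

#' Waveform matrix of a cross-section table
#'
#' @param records tibble with waveform columns `v1 ... vM`.
#' @return Numeric matrix, one row per cross-section.
#' @export
waveform_matrix <- function(records) {
  vcols <- grep("^v[0-9]+$", names(records), value = TRUE)
  if (length(vcols) == 0L) stopf("no waveform columns `v1...vM` found")
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  as.matrix(records[, vcols])
}
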