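#' Run the full PWV pipeline
#'
#' Orchestrates angiogram -> vessel enhancement -> binarization ->
#' skeletonization -> branch selection -> cross-section extraction ->
#' distance assignment -> joint PWV/waveform fit, with per-stage logging and
#' optional artifact output. Input is either a [flow_volume()] (or NIfTI
#' paths with a sidecar) or a [phantom_spec()], in which case the imaging
#' phantom is simulated first and the distance seed defaults to the skeleton
#' voxel nearest the true tube root.
#'
#' @param config a named list or path to a YAML file. Recognized entries:
#'   `flow` (a `flow_volume`), `phantom` (a `phantom_spec`), or `input` (list
#'   of NIfTI paths `magnitude`, `vx`, `vy`, `vz` and `sidecar`);
#'   `scales_mm`, `tau`, `threshold_fraction`; `remove_region` /
#'   `keep_region` (logical array or NIfTI path) with `region_rule`;
#'   `prune_spurs`, `spur_min_voxels`; `seeds` (matrix or list of 1-based
#'   voxel triples); `half_width_mm`, `upsample`, `roi_threshold`,
#'   `search_radius_mm`; `init_pwv`; `out_dir`.
#' @return Object of class `pwv_pipeline`: list with `fit` (a [pwv_fit()]),
#'   `records`, `tree`, `mask`, `cd`, `filtered`, `counts` (per-stage
#'   tallies), `log` (tibble of stage messages), and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    scales_mm = c(0.5, 1, 1.5, 2), tau = 1, threshold_fraction = 0.025,
    region_rule = "any", prune_spurs = TRUE, spur_min_voxels = 3L,
    half_width_mm = 5, upsample = 2L, roi_threshold = 0.5,
    search_radius_mm = 3, init_pwv = 10, out_dir = NULL), config)
  log <- list()
  note <- function(stage, msg, ...) {
    entry <- tibble(stage = stage, message = sprintf(msg, ...),
                    time = format(Sys.time(), "%H:%M:%OS2"))
    log[[length(log) + 1L]] <<- entry
    message(sprintf("[%s] %s", stage, entry$message))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage `%s` failed: %s", stage, conditionMessage(e),
            class = "cerebropwv_stage_error")
    })
  }

  truth <- NULL
  flow <- run_stage("input", {
    if (!is.null(cfg$flow)) cfg$flow
    else if (!is.null(cfg$phantom)) {
      ph <- simulate_flow_volume(cfg$phantom)
      truth <- ph$truth
      ph$flow
    } else if (!is.null(cfg$input)) {
      with(cfg$input, read_flow_nifti(magnitude, vx, vy, vz, sidecar))
    } else stopf("config must supply `flow`, `phantom`, or `input` paths")
  })
  note("input", "%s voxels, %d frames",
       paste(dim(flow$magnitude)[1:3], collapse = "x"), flow$M)

  cd <- run_stage("angio", compute_cd(flow))
  filt <- run_stage("angio", vesselness_filter(cd, cfg$scales_mm, cfg$tau))
  mask <- run_stage("angio", binarize_global(filt, cfg$threshold_fraction))
  note("angio", "mask voxels: %d (%.2f%% of volume)", sum(mask),
       100 * mean(mask))

  sk <- run_stage("skeleton", skeletonize(mask))
  tree <- run_stage("skeleton",
                    build_tree(sk, flow$voxel_size,
                               prune_spurs = cfg$prune_spurs,
                               spur_min_voxels = cfg$spur_min_voxels))
  note("skeleton", "%d centerline voxels, %d branches", nrow(tree$nodes),
       length(unique(stats::na.omit(tree$nodes$branch_id))))

  if (!is.null(cfg$remove_region) || !is.null(cfg$keep_region)) {
    region <- cfg$remove_region %||% cfg$keep_region
    if (is.character(region)) region <- unclass(RNifti::readNifti(region)) > 0
    tree <- run_stage("select",
                      select_branches(tree, region,
                                      mode = if (is.null(cfg$remove_region)) "keep" else "remove",
                                      rule = cfg$region_rule))
    note("select", "%d centerline voxels kept", nrow(tree$nodes))
  }

  seeds <- cfg$seeds
  if (is.null(seeds)) {
    if (is.null(truth)) stopf("config must supply `seeds` for scan data")
    # nearest skeleton voxel to the phantom root
    nd <- tree$nodes
    root <- truth$root_mm
    dd <- (nd$x - root[1L])^2 + (nd$y - root[2L])^2 + (nd$z - root[3L])^2
    seeds <- as.matrix(nd[which.min(dd), c("i", "j", "k")])
    note("distance", "auto seed at phantom root: voxel (%s)",
         paste(seeds[1L, ], collapse = ", "))
  }
  tree <- run_stage("distance", assign_distances(tree, seeds))
  note("distance", "distances %.1f-%.1f mm, %d unreachable voxel(s)",
       min(tree$nodes$distance_mm, na.rm = TRUE),
       max(tree$nodes$distance_mm, na.rm = TRUE),
       sum(!tree$nodes$reachable))

  records <- run_stage("extract",
    extract_cross_sections(flow, cd, tree,
                           half_width_mm = cfg$half_width_mm,
                           upsample = cfg$upsample,
                           roi_threshold = cfg$roi_threshold,
                           search_radius_mm = cfg$search_radius_mm))
  sk_counts <- attr(records, "skipped")
  note("extract", "%d cross-sections kept; skipped: %s", nrow(records),
       paste(sprintf("%s=%d", names(sk_counts), sk_counts), collapse = ", "))

  fit <- run_stage("fit", pwv_fit(records, init_pwv = cfg$init_pwv))
  note("fit", "PWV = %.3f m/s, objective = %.4g, converged = %s",
       fit$pwv, fit$objective, fit$converged)

  counts <- list(mask_voxels = sum(mask), centerline_voxels = nrow(tree$nodes),
                 cross_sections = nrow(records), skipped = as.list(sk_counts))
  out <- structure(list(fit = fit, records = records, tree = tree,
                        mask = mask, cd = cd, filtered = filt,
                        truth = truth, counts = counts,
                        log = dplyr::bind_rows(log), config = cfg),
                   class = "pwv_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(out, cfg$out_dir)
  out
}

#' @export
print.pwv_pipeline <- function(x, ...) {
  cat("<pwv_pipeline>\n")
  print(x$fit)
  invisible(x)
}

# polynomial rolling hash of the serialized config, for run-report provenance
config_hash <- function(cfg) {
  js <- jsonlite::serializeJSON(cfg)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_pipeline_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- x$config$flow$voxel_size %||% attr(x$cd, "voxel_size") %||% 1
  write_volume_nifti(x$cd, file.path(out_dir, "cd.nii.gz"), vs)
  write_volume_nifti(x$filtered, file.path(out_dir, "vesselness.nii.gz"), vs)
  write_volume_nifti(array(as.numeric(x$mask), dim(x$mask)),
                     file.path(out_dir, "mask.nii.gz"), vs)
  write.csv(x$tree$nodes, file.path(out_dir, "centerline.csv"), row.names = FALSE)
  write.csv(x$records, file.path(out_dir, "cross_sections.csv"), row.names = FALSE)
  cfg_for_report <- x$config[setdiff(names(x$config), c("flow", "phantom"))]
  report <- list(
    schema_version = "1.0",
    pwv_m_per_s = x$fit$pwv,
    n_cross_sections = x$fit$n_cross_sections,
    objective = x$fit$objective,
    converged = x$fit$converged,
    V_hat = x$fit$V_hat,
    frame_times = x$fit$frame_times,
    period = x$fit$period,
    waveform_extension = x$fit$diagnostics$extension,
    t_convention = x$fit$diagnostics$t_convention,
    counts = x$counts,
    config = cfg_for_report,
    config_hash = config_hash(cfg_for_report))
  jsonlite::write_json(report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(
    vapply(seq_len(nrow(x$log)), function(i)
      as.character(jsonlite::toJSON(as.list(x$log[i, ]), auto_unbox = TRUE)),
      character(1L)),
    file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' Compare PWV estimates between two cohorts
#'
#' Medians, interquartile ranges, and a two-sided Wilcoxon rank-sum test
#' (exact null for combined n <= 20, normal approximation with continuity
#' correction otherwise).
#'
#' @param group_a,group_b numeric vectors of per-subject PWV estimates, or
#'   data frames with a `pwv` column.
#' @return Object of class `cohort_comparison`: list with `summary` (tibble
#'   of per-group median/IQR), `statistic` (rank-sum W), `p_value`, and
#'   `method`.
#' @export
cohort_compare <- function(group_a, group_b) {
  a <- if (is.data.frame(group_a)) group_a$pwv else as.numeric(group_a)
  b <- if (is.data.frame(group_b)) group_b$pwv else as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 estimates")
  exact <- (length(a) + length(b)) <= 20L
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = TRUE))
  qs <- function(x) quantile(x, c(0.25, 0.75), names = FALSE)
  structure(list(
    summary = tibble(
      group = c("A", "B"), n = c(length(a), length(b)),
      median = c(median(a), median(b)),
      iqr_low = c(qs(a)[1L], qs(b)[1L]),
      iqr_high = c(qs(a)[2L], qs(b)[2L])),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = wt$method),
    class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  s <- x$summary
  for (i in 1:2)
    cat(sprintf("group %s: n = %d, median %.2f (IQR %.2f-%.2f)\n",
                s$group[i], s$n[i], s$median[i], s$iqr_low[i], s$iqr_high[i]))
  cat(sprintf("Wilcoxon rank-sum: W = %g, two-sided p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Pearson correlation utility for consistency analyses
#'
#' @param x,y numeric vectors (e.g. split-half or repeated-extraction PWV
#'   estimates).
#' @return List with `r` and the two-sided `p_value`.
#' @export
pearson_r <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
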