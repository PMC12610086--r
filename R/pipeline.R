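# Per-slide and cohort orchestration.

#' Pipeline configuration
#'
#' All tunable analysis parameters in one place; round-trips through YAML
#' unchanged.
#'
#' @param caliber_threshold_um2 Vessel caliber threshold (square micrometers).
#' @param grid_cell_um Entropy grid cell side.
#' @param hotspot_quantile Hot-spot quantile of nonzero cell counts.
#' @param perivascular_radius_um Perivascular radius.
#' @param heatmap_bandwidth_um Gradient heatmap kernel SD.
#' @param heatmap_cell_um Gradient heatmap cell side.
#' @param segmented_break_quantiles Count quantiles defining segmented-heatmap
#'   breaks.
#' @param necrosis_rule_threshold Necrosis fraction triggering the hypoxic
#'   rule in [classify_pattern()].
#' @param centroid_path Optional path to a centroid YAML (`NULL` = packaged
#'   defaults).
#' @param seed Seed used by any stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(caliber_threshold_um2 = 300, grid_cell_um = 150,
                            hotspot_quantile = 0.95,
                            perivascular_radius_um = 100,
                            heatmap_bandwidth_um = 250, heatmap_cell_um = 100,
                            segmented_break_quantiles = c(0.5, 0.75, 0.9),
                            necrosis_rule_threshold = 0.10,
                            centroid_path = NULL, seed = 1L) {
  vals <- c(caliber_threshold_um2, grid_cell_um, hotspot_quantile,
            perivascular_radius_um, heatmap_bandwidth_um, heatmap_cell_um,
            necrosis_rule_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  structure(list(caliber_threshold_um2 = caliber_threshold_um2,
                 grid_cell_um = grid_cell_um,
                 hotspot_quantile = hotspot_quantile,
                 perivascular_radius_um = perivascular_radius_um,
                 heatmap_bandwidth_um = heatmap_bandwidth_um,
                 heatmap_cell_um = heatmap_cell_um,
                 segmented_break_quantiles = segmented_break_quantiles,
                 necrosis_rule_threshold = necrosis_rule_threshold,
                 centroid_path = centroid_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read or write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$centroid_path <- if (is.null(y$centroid_path) ||
                         identical(y$centroid_path, "")) NULL else y$centroid_path
  do.call(pipeline_config, y)
}

#' @param config A [pipeline_config()].
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$centroid_path <- if (is.null(y$centroid_path)) "" else y$centroid_path
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Analyze one slide
#'
#' Runs the full per-slide workflow: vessel morphometry and census, mitosis
#' grid, entropy, hot spots, perivascular fraction, necrosis fraction, the
#' assembled metric vector and the trophic-pattern call. Optionally writes
#' the morphometry CSV, the metrics row and heatmap PNGs to `out_dir`.
#'
#' @param slide An [annotated_slide()], or a GeoJSON path (then `calibration`
#'   is required and may be a [slide_calibration()] or a sidecar path).
#' @param config A [pipeline_config()].
#' @param calibration Calibration when `slide` is a path.
#' @param out_dir Optional output directory.
#' @return A list of class `slide_result`: `slide_id`, `morphometry`,
#'   `census`, `proliferation`, `metrics` (the metric-vector row plus the
#'   pattern call), `pattern`.
#' @export
run_slide <- function(slide, config = pipeline_config(), calibration = NULL,
                      out_dir = NULL) {
  if (is.character(slide)) {
    if (is.character(calibration)) calibration <- read_calibration(calibration)
    if (!inherits(calibration, "slide_calibration"))
      stop("calibration required when slide is a path", call. = FALSE)
    slide <- read_slide(slide, calibration)
  }
  stopifnot(inherits(slide, "annotated_slide"),
            inherits(config, "pipeline_config"))
  sid <- slide$calibration$slide_id
  morph <- vessel_morphometry(slide, config$caliber_threshold_um2)
  census <- vessel_census(slide, config$caliber_threshold_um2)
  prolif <- proliferation_metrics(slide, config$grid_cell_um,
                                  config$hotspot_quantile,
                                  config$perivascular_radius_um)
  nf <- slide_necrosis_fraction(slide)
  mv <- assemble_metric_vector(census, prolif, nf)
  centroids <- default_pattern_centroids(config$centroid_path)
  call <- classify_pattern(mv, centroids, config$necrosis_rule_threshold)
  metrics <- cbind(mv, data.frame(n_mitoses_tumor = prolif$n_mitoses_tumor,
                                  n_hotspots = prolif$n_hotspots,
                                  pattern = call$pattern,
                                  subtype_label = slide$subtype_label,
                                  stringsAsFactors = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(morph, file.path(out_dir, paste0(sid, "_morphometry.csv")),
              row.names = FALSE)
    write.csv(metrics, file.path(out_dir, paste0(sid, "_metrics.csv")),
              row.names = FALSE)
    grid <- bin_mitoses(slide, config$grid_cell_um)
    pts <- do.call(rbind, lapply(slide$mitoses, function(m) m$location))
    gh <- gradient_heatmap(pts, slide$calibration,
                           config$heatmap_bandwidth_um,
                           config$heatmap_cell_um, channel = "mitoses")
    nz <- grid$counts[grid$counts > 0]
    breaks <- if (length(nz))
      unique(stats::quantile(nz, config$segmented_break_quantiles, type = 7))
      else 1
    sh <- segmented_heatmap(grid, breaks)
    render_overlay(slide, gh, file.path(out_dir, paste0(sid, "_gradient.png")))
    render_overlay(slide, sh, file.path(out_dir, paste0(sid, "_segmented.png")))
  }
  structure(list(slide_id = sid, morphometry = morph, census = census,
                 proliferation = prolif, metrics = metrics,
                 pattern = call$pattern),
            class = "slide_result")
}

#' Analyze a cohort
#'
#' Runs [run_slide()] over a cohort given either a `generate_cohort()` result,
#' a list of slides, or a manifest data.frame with `annotation_path` and
#' `calibration_path` columns. Slides that fail validation are collected in a
#' `failures` section; the rest are still processed.
#'
#' @param cohort Cohort input (see above).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (cohort CSV + summary CSV).
#' @return A list of class `cohort_result`: `metrics` (one row per slide),
#'   `summary` (per-subtype mean/SD via [cohort_summary()]), `failures`
#'   (data.frame of slide_id + error message).
#' @export
run_cohort <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  slides <- NULL
  manifest <- NULL
  if (is.list(cohort) && !is.null(cohort$slides)) {
    slides <- cohort$slides
  } else if (is.data.frame(cohort)) {
    manifest <- cohort
  } else if (is.list(cohort)) {
    slides <- cohort
  } else stop("unsupported cohort input", call. = FALSE)
  n <- if (!is.null(slides)) length(slides) else nrow(manifest)
  rows <- list(); fails <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (!is.null(slides)) run_slide(slides[[i]], config)
      else run_slide(manifest$annotation_path[i], config,
                     calibration = manifest$calibration_path[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      sid <- if (!is.null(slides))
        slides[[i]]$calibration$slide_id else manifest$slide_id[i]
      fails[[length(fails) + 1L]] <-
        data.frame(slide_id = sid, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res$metrics
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (!is.null(metrics))
    cohort_summary(metrics, metrics$subtype_label) else NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(slide_id = character(0), error = character(0))
  if (!is.null(out_dir) && !is.null(metrics)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "cohort_metrics.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
  }
  structure(list(metrics = metrics, summary = summary, failures = failures),
            class = "cohort_result")
}
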