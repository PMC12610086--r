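# Per-slide metric vector assembly and trophic-pattern classification.

metric_fields <- c("entropy_dits", "density_pct", "n_small_center",
                   "n_small_periphery", "n_large_center", "n_large_periphery",
                   "necrosis_fraction", "perivascular_fraction")

#' Assemble the per-slide vascularization-proliferation metric vector
#'
#' Joins the vessel census and proliferation metrics of one slide with its
#' necrosis fraction into the flat feature vector used for trophic-pattern
#' classification.
#'
#' @param census A [vessel_census()] result.
#' @param prolif A [proliferation_metrics()] result from the same slide.
#' @param necrosis_fraction Necrosis area / tumor area, in `[0, 1]` (see
#'   [slide_necrosis_fraction()]).
#' @return A one-row data.frame of class `metric_vector` with columns
#'   `slide_id`, `entropy_dits`, `density_pct`, the four compartment-caliber
#'   counts, `necrosis_fraction`, `perivascular_fraction`.
#' @export
assemble_metric_vector <- function(census, prolif, necrosis_fraction = 0) {
  stopifnot(inherits(census, "vessel_census"),
            inherits(prolif, "proliferation_metrics"))
  if (!identical(census$slide_id, prolif$slide_id))
    stop("census and proliferation metrics come from different slides (",
         census$slide_id, " vs ", prolif$slide_id, ")", call. = FALSE)
  if (necrosis_fraction < 0 || necrosis_fraction > 1)
    stop("necrosis_fraction must lie in [0, 1]", call. = FALSE)
  out <- data.frame(
    slide_id = census$slide_id,
    entropy_dits = prolif$entropy_dits,
    density_pct = census$relative_area_density_pct,
    n_small_center = census$n_small_center,
    n_small_periphery = census$n_small_periphery,
    n_large_center = census$n_large_center,
    n_large_periphery = census$n_large_periphery,
    necrosis_fraction = necrosis_fraction,
    perivascular_fraction = prolif$perivascular_fraction,
    stringsAsFactors = FALSE)
  class(out) <- c("metric_vector", class(out))
  out
}

#' Necrosis fraction of a slide
#'
#' Total annotated necrosis area divided by total tumor area.
#'
#' @param slide An [annotated_slide()].
#' @return A fraction in `[0, 1]` (clamped at 1 for overfull annotation).
#' @export
slide_necrosis_fraction <- function(slide) {
  stopifnot(inherits(slide, "annotated_slide"))
  a_t <- sum(vapply(slide$regions$tumor, poly_area, numeric(1)))
  if (a_t <= 0) stop("zero tumor area", call. = FALSE)
  if (!length(slide$necrosis)) return(0)
  a_n <- sum(vapply(slide$necrosis, poly_area, numeric(1)))
  min(1, a_n / a_t)
}

#' Packaged trophic-pattern centroid table
#'
#' Loads the default pattern centroids: per-pattern means and SDs for each
#' metric-vector field. Entropy, density and the four compartment counts are
#' the published per-subtype cohort statistics; necrosis and perivascular
#' fields are reconstruction constants matched to the synthetic generator
#' (documented in the centroid YAML itself).
#'
#' @param path Optional path to an alternative centroid YAML.
#' @return A data.frame with columns `pattern`, `subtype`, then
#'   `<field>_mean` and `<field>_sd` for each metric field.
#' @export
default_pattern_centroids <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pattern_centroids.yaml",
                        package = "mitovasc", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  rows <- lapply(y$centroids, function(ct) {
    r <- data.frame(pattern = ct$pattern, subtype = ct$subtype,
                    stringsAsFactors = FALSE)
    for (f in metric_fields) {
      r[[paste0(f, "_mean")]] <- as.numeric(ct[[f]][["mean"]])
      r[[paste0(f, "_sd")]] <- as.numeric(ct[[f]][["sd"]])
    }
    r
  })
  do.call(rbind, rows)
}

#' Classify a metric vector into a trophic pattern
#'
#' Two-stage rule: (i) a slide with necrosis fraction at or above
#' `necrosis_rule_threshold` AND tumor vessel density below the hypoxic
#' centroid's density mean is called `hypoxic` outright (the necrosis-defined
#' pattern); (ii) otherwise the vector is assigned the nearest centroid by
#' Euclidean distance in z-space, each field standardized by the centroid
#' table's pooled SD. Ties break by centroid table order.
#'
#' @param v A [assemble_metric_vector()] row (or a one-row data.frame with
#'   the metric fields).
#' @param centroids Centroid table as from [default_pattern_centroids()].
#' @param necrosis_rule_threshold Necrosis fraction triggering rule (i);
#'   default 0.10.
#' @return A list: `pattern` (the call), `rule` (`"necrosis"` or
#'   `"nearest_centroid"`), and `scores` (named z-space distance per pattern;
#'   smaller is closer).
#' @export
classify_pattern <- function(v, centroids = default_pattern_centroids(),
                             necrosis_rule_threshold = 0.10) {
  if (nrow(centroids) < 2L) stop("need at least 2 centroids", call. = FALSE)
  x <- unlist(v[1, metric_fields])
  sd_cols <- paste0(metric_fields, "_sd")
  mean_cols <- paste0(metric_fields, "_mean")
  pooled_sd <- sqrt(colMeans(as.matrix(centroids[, sd_cols])^2))
  if (any(pooled_sd <= 0))
    stop("degenerate (non-positive) pooled SD in centroid table", call. = FALSE)
  M <- as.matrix(centroids[, mean_cols])
  z <- sweep(sweep(M, 2, x, "-"), 2, pooled_sd, "/")
  d <- sqrt(rowSums(z^2))
  names(d) <- centroids$pattern
  hyp <- which(centroids$pattern == "hypoxic")
  if (length(hyp) == 1L &&
      x["necrosis_fraction"] >= necrosis_rule_threshold &&
      x["density_pct"] < centroids$density_pct_mean[hyp])
    return(list(pattern = "hypoxic", rule = "necrosis", scores = d))
  list(pattern = centroids$pattern[which.min(d)], rule = "nearest_centroid",
       scores = d)
}

#' Per-group mean and SD summary of a cohort
#'
#' @param vectors A data.frame of metric vectors (rows = slides) containing
#'   the metric fields.
#' @param labels Character vector of group labels (e.g. histologic subtype),
#'   one per row.
#' @return A data.frame with one row per group and, for each metric field,
#'   `<field>_mean` and `<field>_sd` (sample SD, n-1 denominator; `NA` for
#'   groups of size 1), plus `n`.
#' @export
cohort_summary <- function(vectors, labels) {
  if (nrow(vectors) != length(labels))
    stop("labels must align with vectors", call. = FALSE)
  fields <- intersect(metric_fields, names(vectors))
  groups <- unique(labels)
  rows <- lapply(groups, function(g) {
    sub <- vectors[labels == g, fields, drop = FALSE]
    r <- data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE)
    for (f in fields) {
      r[[paste0(f, "_mean")]] <- mean(sub[[f]])
      r[[paste0(f, "_sd")]] <- if (nrow(sub) >= 2L) sd(sub[[f]]) else NA_real_
    }
    r
  })
  do.call(rbind, rows)
}
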