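# Per-vessel morphometry and the per-slide vessel census.

#' Polygon area in square micrometers
#'
#' Shoelace area in squared pixels scaled by the squared pixel size.
#'
#' @param boundary Simple polygon (n x 2 matrix, pixel coordinates).
#' @param calibration A [slide_calibration()].
#' @return Area in square micrometers (strictly positive).
#' @export
polygon_area_um2 <- function(boundary, calibration) {
  stopifnot(inherits(calibration, "slide_calibration"))
  boundary <- as_poly_matrix(boundary)
  a <- poly_area(boundary) * calibration$microns_per_pixel^2
  if (a <= 0) stop("degenerate polygon: zero area", call. = FALSE)
  a
}

#' Classify vessel caliber by mask area
#'
#' Vessels are split into small and large at an area threshold (default
#' 300 square micrometers, separating capillaries from venules/arterioles).
#' A vessel exactly at the threshold is classified small.
#'
#' @param area_um2 Vessel area(s) in square micrometers (vectorized).
#' @param threshold_um2 Positive caliber threshold.
#' @return Character vector of `"small"` / `"large"`.
#' @export
classify_caliber <- function(area_um2, threshold_um2 = 300) {
  if (!is.numeric(threshold_um2) || threshold_um2 <= 0)
    stop("threshold_um2 must be positive", call. = FALSE)
  if (any(area_um2 <= 0)) stop("area_um2 must be positive", call. = FALSE)
  ifelse(area_um2 > threshold_um2, "large", "small")
}

#' Assign a vessel to the tumor center, periphery, or outside
#'
#' Compartment membership is decided by the vessel centroid: `center` if it
#' lies in a tumor polygon, `periphery` if in a peritumoral polygon,
#' `outside` otherwise. Centroid membership is deterministic and robust for
#' vessels straddling region boundaries.
#'
#' @param vessel A [vessel_annotation()].
#' @param regions A [region_set()].
#' @return One of `"center"`, `"periphery"`, `"outside"`.
#' @export
assign_compartment <- function(vessel, regions) {
  stopifnot(inherits(vessel, "vessel_annotation"), inherits(regions, "region_set"))
  ct <- matrix(poly_centroid(vessel$boundary), ncol = 2)
  if (any(points_in_any(ct, regions$tumor))) return("center")
  if (any(points_in_any(ct, regions$peritumoral))) return("periphery")
  "outside"
}

#' Per-vessel morphometry table
#'
#' One row per vessel: area, rotating-calipers Feret diameters, caliber class
#' and compartment.
#'
#' @param slide An [annotated_slide()].
#' @param threshold_um2 Caliber threshold, see [classify_caliber()].
#' @return A data.frame with columns `vessel_id`, `area_um2`, `feret_min_um`,
#'   `feret_max_um`, `caliber`, `compartment`, `invasive`.
#' @export
vessel_morphometry <- function(slide, threshold_um2 = 300) {
  stopifnot(inherits(slide, "annotated_slide"))
  if (!length(slide$vessels))
    return(data.frame(vessel_id = character(0), area_um2 = numeric(0),
                      feret_min_um = numeric(0), feret_max_um = numeric(0),
                      caliber = character(0), compartment = character(0),
                      invasive = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(slide$vessels, function(v) {
    a <- polygon_area_um2(v$boundary, slide$calibration)
    fer <- feret_diameters(v$boundary, slide$calibration)
    data.frame(vessel_id = v$id, area_um2 = a,
               feret_min_um = unname(fer[1]), feret_max_um = unname(fer[2]),
               caliber = classify_caliber(a, threshold_um2),
               compartment = assign_compartment(v, slide$regions),
               invasive = v$invasive, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-slide vessel census
#'
#' Counts vessels per compartment-by-caliber cell and computes the relative
#' area density in the tumor: total vessel mask area of center-compartment
#' vessels as a percentage of total tumor area. Vessels outside both regions
#' are excluded from the four counts.
#'
#' @param slide An [annotated_slide()].
#' @param threshold_um2 Caliber threshold in square micrometers.
#' @return A list of class `vessel_census`: `n_small_center`,
#'   `n_small_periphery`, `n_large_center`, `n_large_periphery`,
#'   `vessel_area_center_um2`, `tumor_area_um2`, `relative_area_density_pct`,
#'   and `slide_id`.
#' @export
vessel_census <- function(slide, threshold_um2 = 300) {
  stopifnot(inherits(slide, "annotated_slide"))
  tumor_area <- sum(vapply(slide$regions$tumor, poly_area, numeric(1))) *
    slide$calibration$microns_per_pixel^2
  if (tumor_area <= 0)
    stop("zero tumor area: relative density undefined", call. = FALSE)
  m <- vessel_morphometry(slide, threshold_um2)
  cnt <- function(cal, comp) sum(m$caliber == cal & m$compartment == comp)
  area_center <- sum(m$area_um2[m$compartment == "center"])
  structure(list(
    n_small_center = cnt("small", "center"),
    n_small_periphery = cnt("small", "periphery"),
    n_large_center = cnt("large", "center"),
    n_large_periphery = cnt("large", "periphery"),
    vessel_area_center_um2 = area_center,
    tumor_area_um2 = tumor_area,
    relative_area_density_pct = 100 * area_center / tumor_area,
    slide_id = slide$calibration$slide_id), class = "vessel_census")
}

#' @export
print.vessel_census <- function(x, ...) {
  cat(sprintf(paste0("<vessel_census> %s: small c/p %d/%d, large c/p %d/%d, ",
                     "density %.4f%%\n"),
              x$slide_id, x$n_small_center, x$n_small_periphery,
              x$n_large_center, x$n_large_periphery,
              x$relative_area_density_pct))
  invisible(x)
}
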