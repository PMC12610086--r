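# Slide annotation containers, validation, GeoJSON I/O, tiling.

#' Slide calibration record
#'
#' Pixel dimensions and physical resolution of one whole-slide image. All
#' geometry in an [annotated_slide()] is expressed in pixels; the calibration
#' carries the microns-per-pixel factor that makes downstream metrics
#' magnification independent.
#'
#' @param slide_id Character scalar identifying the slide.
#' @param width_px,height_px Positive integers, slide extent in pixels.
#' @param microns_per_pixel Positive real, physical size of one pixel in
#'   micrometers.
#' @return An object of class `slide_calibration`.
#' @export
#' @examples
#' slide_calibration("S1", 50000, 50000, 0.5)
slide_calibration <- function(slide_id, width_px, height_px, microns_per_pixel) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  width_px <- as.numeric(width_px); height_px <- as.numeric(height_px)
  if (width_px < 1 || height_px < 1 || width_px != round(width_px) ||
      height_px != round(height_px))
    stop("width_px and height_px must be positive integers", call. = FALSE)
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a positive real", call. = FALSE)
  structure(list(slide_id = slide_id, width_px = width_px,
                 height_px = height_px,
                 microns_per_pixel = microns_per_pixel),
            class = "slide_calibration")
}

#' @export
print.slide_calibration <- function(x, ...) {
  cat(sprintf("<slide_calibration> %s: %d x %d px @ %g um/px\n",
              x$slide_id, x$width_px, x$height_px, x$microns_per_pixel))
  invisible(x)
}

#' Read or write a calibration sidecar (YAML or CSV)
#'
#' The sidecar stores `slide_id`, `width_px`, `height_px` and
#' `microns_per_pixel`; the format is chosen by file extension (`.yaml`/`.yml`
#' or `.csv`).
#'
#' @param path File path.
#' @return `read_calibration()` returns a [slide_calibration()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rec <- yaml::read_yaml(path)
  } else {
    rec <- as.list(read.csv(path, stringsAsFactors = FALSE)[1, ])
  }
  slide_calibration(as.character(rec$slide_id), rec$width_px, rec$height_px,
                    rec$microns_per_pixel)
}

#' @param calibration A [slide_calibration()].
#' @rdname read_calibration
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "slide_calibration"))
  rec <- unclass(calibration)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(rec, path)
  } else {
    write.csv(as.data.frame(rec), path, row.names = FALSE)
  }
  invisible(path)
}

#' Tumor and peritumoral region set
#'
#' @param tumor,peritumoral Lists of simple polygons (n x 2 numeric matrices,
#'   pixel coordinates, implicitly closed).
#' @return An object of class `region_set`.
#' @export
region_set <- function(tumor, peritumoral) {
  check_polys <- function(polys, what) {
    if (is.matrix(polys)) polys <- list(polys)
    polys <- lapply(polys, as_poly_matrix, what = what)
    for (i in seq_along(polys)) {
      p <- polys[[i]]
      if (nrow(p) < 3L || poly_area(p) <= 0)
        stop(what, " polygon ", i, " is degenerate (zero area)", call. = FALSE)
      if (!poly_is_simple(p))
        stop(what, " polygon ", i, " is self-intersecting", call. = FALSE)
    }
    polys
  }
  tumor <- check_polys(tumor, "tumor")
  peritumoral <- check_polys(peritumoral, "peritumoral")
  # necessary (cheap) non-overlap check: no polygon's centroid strictly inside
  # a polygon of the other group
  for (tp in tumor) {
    ct <- matrix(poly_centroid(tp), ncol = 2)
    if (any(vapply(peritumoral, function(pp) points_in_poly(ct, pp), logical(1))))
      stop("tumor and peritumoral polygons overlap", call. = FALSE)
  }
  structure(list(tumor = tumor, peritumoral = peritumoral), class = "region_set")
}

#' Single vessel annotation
#'
#' @param id Character vessel identifier.
#' @param boundary Simple polygon (>= 3 vertices, n x 2 matrix, pixel coords).
#' @param invasive Logical flag: lymphovascular invasion present.
#' @return An object of class `vessel_annotation`.
#' @export
vessel_annotation <- function(id, boundary, invasive = FALSE) {
  boundary <- as_poly_matrix(boundary, paste0("vessel ", id, " boundary"))
  if (nrow(boundary) < 3L)
    stop("vessel ", id, ": boundary needs >= 3 vertices", call. = FALSE)
  if (poly_area(boundary) <= 0)
    stop("vessel ", id, ": zero-area boundary", call. = FALSE)
  if (!poly_is_simple(boundary))
    stop("vessel ", id, ": boundary is self-intersecting", call. = FALSE)
  structure(list(id = as.character(id), boundary = boundary,
                 invasive = isTRUE(invasive)),
            class = "vessel_annotation")
}

#' Single mitotic-figure annotation
#'
#' Detections without a confidence score are treated as confirmed ground truth
#' (score 1).
#'
#' @param location Numeric length-2 point (pixel coordinates).
#' @param score Detection confidence in `[0, 1]`.
#' @return An object of class `mitosis_annotation`.
#' @export
mitosis_annotation <- function(location, score = 1) {
  location <- as.numeric(location)
  if (length(location) != 2L || anyNA(location))
    stop("location must be a finite 2-D point", call. = FALSE)
  if (!is.numeric(score) || is.na(score) || score < 0 || score > 1)
    stop("score must lie in [0, 1]", call. = FALSE)
  structure(list(location = location, score = as.numeric(score)),
            class = "mitosis_annotation")
}

#' Annotated slide: the per-WSI analysis unit
#'
#' Bundles one slide's calibration, tumor/peritumoral regions, vessel
#' polygons, mitotic-figure points and optional necrosis polygons. All
#' geometry must fall within the calibrated slide bounds.
#'
#' @param calibration A [slide_calibration()].
#' @param regions A [region_set()].
#' @param vessels List of [vessel_annotation()] objects.
#' @param mitoses List of [mitosis_annotation()] objects.
#' @param necrosis List of simple polygons (possibly empty).
#' @param subtype_label Optional character label (histologic subtype).
#' @return An object of class `annotated_slide`.
#' @export
annotated_slide <- function(calibration, regions, vessels = list(),
                            mitoses = list(), necrosis = list(),
                            subtype_label = NA_character_) {
  stopifnot(inherits(calibration, "slide_calibration"),
            inherits(regions, "region_set"))
  for (v in vessels) if (!inherits(v, "vessel_annotation"))
    stop("vessels must be vessel_annotation objects", call. = FALSE)
  for (m in mitoses) if (!inherits(m, "mitosis_annotation"))
    stop("mitoses must be mitosis_annotation objects", call. = FALSE)
  if (is.matrix(necrosis)) necrosis <- list(necrosis)
  necrosis <- lapply(necrosis, as_poly_matrix, what = "necrosis")
  slide <- structure(
    list(calibration = calibration, regions = regions, vessels = vessels,
         mitoses = mitoses, necrosis = necrosis,
         subtype_label = as.character(subtype_label)),
    class = "annotated_slide")
  validate_slide_bounds(slide)
  slide
}

validate_slide_bounds <- function(slide) {
  W <- slide$calibration$width_px; H <- slide$calibration$height_px
  inb <- function(p) all(p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H)
  for (p in c(slide$regions$tumor, slide$regions$peritumoral, slide$necrosis))
    if (!inb(p)) stop("region geometry outside slide bounds", call. = FALSE)
  for (v in slide$vessels)
    if (!inb(v$boundary))
      stop("vessel ", v$id, " outside slide bounds", call. = FALSE)
  for (m in slide$mitoses)
    if (!inb(matrix(m$location, ncol = 2)))
      stop("mitosis outside slide bounds", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.annotated_slide <- function(x, ...) {
  cat(sprintf(paste0("<annotated_slide> %s (%s): %d tumor / %d peritumoral ",
                     "polygons, %d vessels, %d mitoses, %d necrosis\n"),
              x$calibration$slide_id,
              if (is.na(x$subtype_label)) "unlabelled" else x$subtype_label,
              length(x$regions$tumor), length(x$regions$peritumoral),
              length(x$vessels), length(x$mitoses), length(x$necrosis)))
  invisible(x)
}

geojson_polygon_coords <- function(p) {
  ring <- rbind(p, p[1, , drop = FALSE])   # GeoJSON rings are closed
  list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
}

#' Write an annotated slide as a GeoJSON FeatureCollection
#'
#' One feature per annotated object. The feature `class` property is one of
#' `tumor`, `peritumoral`, `vessel`, `mitosis`, `necrosis`; vessels carry an
#' `invasive` property, mitoses a `score`. Coordinates are written at full
#' precision (values with at most three decimals round-trip exactly).
#'
#' @param slide An [annotated_slide()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_slide()]
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "annotated_slide"))
  feats <- list()
  add <- function(geom_type, coords, props) {
    feats[[length(feats) + 1L]] <<- list(
      type = "Feature",
      geometry = list(type = geom_type, coordinates = coords),
      properties = props)
  }
  for (i in seq_along(slide$regions$tumor))
    add("Polygon", geojson_polygon_coords(slide$regions$tumor[[i]]),
        list(class = "tumor", id = paste0("tumor_", i)))
  for (i in seq_along(slide$regions$peritumoral))
    add("Polygon", geojson_polygon_coords(slide$regions$peritumoral[[i]]),
        list(class = "peritumoral", id = paste0("peritumoral_", i)))
  for (v in slide$vessels)
    add("Polygon", geojson_polygon_coords(v$boundary),
        list(class = "vessel", id = v$id, invasive = v$invasive))
  for (i in seq_along(slide$mitoses)) {
    m <- slide$mitoses[[i]]
    add("Point", m$location,
        list(class = "mitosis", id = paste0("mitosis_", i), score = m$score))
  }
  for (i in seq_along(slide$necrosis))
    add("Polygon", geojson_polygon_coords(slide$necrosis[[i]]),
        list(class = "necrosis", id = paste0("necrosis_", i)))
  fc <- list(type = "FeatureCollection",
             properties = list(slide_id = slide$calibration$slide_id,
                               subtype_label = slide$subtype_label),
             features = feats)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  con <- file(path, open = "wb")          # fixed newline, byte-stable output
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an annotated slide from a GeoJSON FeatureCollection
#'
#' Accepts the dialect written by [write_slide()]: a FeatureCollection whose
#' features carry a `class` property in `tumor`, `peritumoral`, `vessel`,
#' `mitosis`, `necrosis`. Unknown classes and malformed or out-of-bounds
#' geometry are rejected.
#'
#' @param path GeoJSON file path.
#' @param calibration A [slide_calibration()] sidecar record for the slide.
#' @return A validated [annotated_slide()].
#' @export
read_slide <- function(path, calibration) {
  stopifnot(inherits(calibration, "slide_calibration"))
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  tumor <- list(); peri <- list(); necro <- list()
  vessels <- list(); mitoses <- list()
  coords_matrix <- function(coords, fid) {
    ring <- coords[[1]]
    m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    if (ncol(m) != 2 || anyNA(m))
      stop("malformed polygon geometry in feature ", fid, call. = FALSE)
    # drop the closing vertex (implicit-closure convention)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  for (f in fc$features) {
    props <- f$properties
    fid <- if (!is.null(props$id)) props$id else "<no id>"
    cls <- props$class
    if (is.null(cls)) stop("feature ", fid, " has no class property", call. = FALSE)
    switch(cls,
      tumor = { tumor[[length(tumor) + 1L]] <- coords_matrix(f$geometry$coordinates, fid) },
      peritumoral = { peri[[length(peri) + 1L]] <- coords_matrix(f$geometry$coordinates, fid) },
      necrosis = { necro[[length(necro) + 1L]] <- coords_matrix(f$geometry$coordinates, fid) },
      vessel = {
        inv <- props$invasive
        if (is.null(inv)) stop("vessel ", fid, " lacks invasive flag", call. = FALSE)
        vessels[[length(vessels) + 1L]] <-
          vessel_annotation(fid, coords_matrix(f$geometry$coordinates, fid),
                            isTRUE(inv))
      },
      mitosis = {
        loc <- as.numeric(unlist(f$geometry$coordinates))
        score <- if (is.null(props$score)) 1 else as.numeric(props$score)
        mitoses[[length(mitoses) + 1L]] <- mitosis_annotation(loc, score)
      },
      stop("unknown feature class '", cls, "' in feature ", fid, call. = FALSE)
    )
  }
  subtype <- fc$properties$subtype_label
  if (is.null(subtype)) subtype <- NA_character_
  annotated_slide(calibration, region_set(tumor, peri), vessels, mitoses,
                  necro, subtype)
}

#' Check the 1:1 tumor / peritumoral area design
#'
#' Annotation protocols aim for equal tumor and peritumoral areas on each
#' slide. This reports the achieved ratio; deviations are a warning-level
#' finding, not an error, since real annotations drift from the design.
#'
#' @param regions A [region_set()].
#' @param tolerance Maximum allowed `|ratio - 1|` for a pass.
#' @return A list with `ratio` (total peritumoral area / total tumor area),
#'   `pass`, and the two areas in squared pixels.
#' @export
check_region_balance <- function(regions, tolerance = 0.05) {
  stopifnot(inherits(regions, "region_set"))
  a_t <- sum(vapply(regions$tumor, poly_area, numeric(1)))
  a_p <- sum(vapply(regions$peritumoral, poly_area, numeric(1)))
  if (a_t <= 0) stop("tumor area is zero: balance ratio undefined", call. = FALSE)
  ratio <- a_p / a_t
  list(ratio = ratio, pass = abs(ratio - 1) <= tolerance,
       tumor_area_px2 = a_t, peritumoral_area_px2 = a_p)
}

#' Sliding-window tile coordinates
#'
#' Generates the tile rectangles of a sliding-window pass over the slide with
#' fractional overlap (default 10%). The last row and column are clamped to
#' the slide boundary so the union of tiles covers every pixel.
#'
#' @param calibration A [slide_calibration()].
#' @param tile_px Tile side length in pixels.
#' @param overlap_fraction Fraction of tile side shared by adjacent tiles,
#'   in `[0, 1)`.
#' @return A data.frame with columns `x0`, `y0`, `x1`, `y1` (0-based,
#'   right/bottom exclusive).
#' @export
sliding_window <- function(calibration, tile_px, overlap_fraction = 0.1) {
  stopifnot(inherits(calibration, "slide_calibration"))
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  W <- calibration$width_px; H <- calibration$height_px
  if (tile_px > min(W, H)) stop("tile_px exceeds slide extent", call. = FALSE)
  stride <- max(1L, round(tile_px * (1 - overlap_fraction)))
  starts <- function(extent) {
    s <- seq(0L, max(0L, extent - tile_px), by = stride)
    if (s[length(s)] + tile_px < extent) s <- c(s, extent - tile_px)
    s
  }
  xs <- starts(W); ys <- starts(H)
  g <- expand.grid(x0 = xs, y0 = ys)
  data.frame(x0 = g$x0, y0 = g$y0, x1 = g$x0 + tile_px, y1 = g$y0 + tile_px)
}
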