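# Spatial statistics of mitotic figures: grid binning, entropy (dits),
# hot spots, perivascular clustering.

#' Bin tumor mitoses onto a regular grid
#'
#' Lays a square grid of physical cell size over the tumor bounding box and
#' assigns each tumor mitosis to exactly one cell by floor division of its
#' coordinates (points on a cell boundary go to the higher-index cell).
#' Mitoses outside the tumor region are excluded.
#'
#' @param slide An [annotated_slide()] with a non-empty tumor region.
#' @param cell_size_um Grid cell side in micrometers (default 150).
#' @return An object of class `mitosis_grid`: `counts` (nx x ny integer
#'   matrix), `tumor_mask` (logical matrix: cell center inside tumor, or cell
#'   occupied by a tumor mitosis), `cell_size_um`, `origin` (pixel
#'   coordinates of the grid origin), `n_mitoses_tumor`.
#' @export
bin_mitoses <- function(slide, cell_size_um = 150) {
  stopifnot(inherits(slide, "annotated_slide"))
  if (!is.numeric(cell_size_um) || cell_size_um <= 0)
    stop("cell_size_um must be positive", call. = FALSE)
  if (!length(slide$regions$tumor)) stop("tumor region is empty", call. = FALSE)
  mpp <- slide$calibration$microns_per_pixel
  cell_px <- cell_size_um / mpp
  bb <- poly_bbox(slide$regions$tumor)
  nx <- max(1L, floor((bb["xmax"] - bb["xmin"]) / cell_px) + 1L)
  ny <- max(1L, floor((bb["ymax"] - bb["ymin"]) / cell_px) + 1L)
  pts <- do.call(rbind, lapply(slide$mitoses, function(m) m$location))
  counts <- matrix(0L, nx, ny)
  if (!is.null(pts) && nrow(pts)) {
    keep <- points_in_any(pts, slide$regions$tumor)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts)) {
      ix <- pmin(nx - 1L, pmax(0L, floor((pts[, 1] - bb["xmin"]) / cell_px)))
      iy <- pmin(ny - 1L, pmax(0L, floor((pts[, 2] - bb["ymin"]) / cell_px)))
      counts <- matrix(tabulate(ix + nx * iy + 1L, nbins = nx * ny), nx, ny)
    }
  }
  cx <- bb["xmin"] + (seq_len(nx) - 0.5) * cell_px
  cy <- bb["ymin"] + (seq_len(ny) - 0.5) * cell_px
  centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  mask <- matrix(points_in_any(centers, slide$regions$tumor), nx, ny)
  mask <- mask | counts > 0L   # edge cells holding a tumor mitosis stay in
  structure(list(counts = counts, tumor_mask = mask,
                 cell_size_um = cell_size_um,
                 origin = unname(c(bb["xmin"], bb["ymin"])),
                 n_mitoses_tumor = sum(counts)),
            class = "mitosis_grid")
}

#' Spatial entropy of mitoses in dits
#'
#' Shannon entropy of the grid-cell occupancy distribution with base-10
#' logarithm (units: dits, decimal digits of information). With cell counts
#' c_i over tumor cells and N their total, the entropy is
#' `-sum(p_i * log10(p_i))` over occupied cells, `p_i = c_i / N`. Low values
#' indicate clustered proliferation, high values a diffuse pattern. An empty
#' grid (no tumor mitoses) has entropy 0 by convention.
#'
#' @param grid A [bin_mitoses()] result.
#' @return Entropy in dits, bounded by `log10(number of tumor cells)`.
#' @export
mitoses_entropy <- function(grid) {
  stopifnot(inherits(grid, "mitosis_grid"))
  cc <- grid$counts[grid$tumor_mask]
  n <- sum(cc)
  if (n == 0) return(0)
  p <- cc[cc > 0] / n
  -sum(p * log10(p))
}

#' Detect mitotic hot spots
#'
#' Hot spots are grid cells whose count reaches the given quantile of the
#' nonzero cell counts and is at least 2 (a single mitosis is never a hot
#' spot). Returns an empty set when the slide has no mitoses.
#'
#' @param grid A [bin_mitoses()] result.
#' @param quantile Quantile of nonzero cell counts in (0, 1); default 0.95.
#' @return data.frame with columns `ix`, `iy` (1-based cell indices) and
#'   `count`.
#' @export
detect_hotspots <- function(grid, quantile = 0.95) {
  stopifnot(inherits(grid, "mitosis_grid"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stop("quantile must lie in (0, 1)", call. = FALSE)
  nz <- grid$counts[grid$counts > 0L]
  empty <- data.frame(ix = integer(0), iy = integer(0), count = integer(0))
  if (!length(nz)) return(empty)
  thr <- max(2, stats::quantile(nz, quantile, type = 7))
  idx <- which(grid$counts >= thr, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  data.frame(ix = idx[, 1], iy = idx[, 2],
             count = grid$counts[idx])
}

#' Fraction of tumor mitoses near a vessel
#'
#' Fraction of tumor mitoses whose distance to the nearest vessel boundary is
#' at most `radius_um`. Mitoses inside a vessel mask count (distance 0 side).
#' Returns 0 when the slide has no vessels or no tumor mitoses.
#'
#' @param slide An [annotated_slide()].
#' @param radius_um Perivascular radius in micrometers (default 100).
#' @return A fraction in `[0, 1]`.
#' @export
perivascular_fraction <- function(slide, radius_um = 100) {
  stopifnot(inherits(slide, "annotated_slide"))
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("radius_um must be positive", call. = FALSE)
  pts <- do.call(rbind, lapply(slide$mitoses, function(m) m$location))
  if (is.null(pts) || !nrow(pts) || !length(slide$vessels)) return(0)
  keep <- points_in_any(pts, slide$regions$tumor)
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(0)
  r_px <- radius_um / slide$calibration$microns_per_pixel
  near <- rep(FALSE, nrow(pts))
  for (v in slide$vessels) {
    idx <- which(!near)
    if (!length(idx)) break
    bb <- poly_bbox(v$boundary)
    cand <- idx[pts[idx, 1] >= bb["xmin"] - r_px & pts[idx, 1] <= bb["xmax"] + r_px &
                pts[idx, 2] >= bb["ymin"] - r_px & pts[idx, 2] <= bb["ymax"] + r_px]
    if (!length(cand)) next
    d <- dist_to_poly_boundary(pts[cand, , drop = FALSE], v$boundary)
    inside <- points_in_poly(pts[cand, , drop = FALSE], v$boundary)
    near[cand] <- d <= r_px | inside
  }
  mean(near)
}

#' Per-slide proliferation metrics
#'
#' Convenience wrapper computing the grid, entropy, hot spots and
#' perivascular fraction in one call.
#'
#' @param slide An [annotated_slide()].
#' @param cell_size_um Grid cell side in micrometers.
#' @param hotspot_quantile See [detect_hotspots()].
#' @param radius_um See [perivascular_fraction()].
#' @return A list of class `proliferation_metrics`: `entropy_dits`,
#'   `n_mitoses_tumor`, `hotspot_cells`, `n_hotspots`,
#'   `perivascular_fraction`, `slide_id`.
#' @export
proliferation_metrics <- function(slide, cell_size_um = 150,
                                  hotspot_quantile = 0.95, radius_um = 100) {
  grid <- bin_mitoses(slide, cell_size_um)
  hs <- detect_hotspots(grid, hotspot_quantile)
  structure(list(entropy_dits = mitoses_entropy(grid),
                 n_mitoses_tumor = grid$n_mitoses_tumor,
                 hotspot_cells = hs, n_hotspots = nrow(hs),
                 perivascular_fraction = perivascular_fraction(slide, radius_um),
                 slide_id = slide$calibration$slide_id),
            class = "proliferation_metrics")
}
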