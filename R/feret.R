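# Rotating-calipers Feret diameters.

#' Minimum and maximum Feret diameters of a polygon
#'
#' Feret diameters are the extents of a shape projected onto a direction; the
#' minimum and maximum over all directions characterize vessel caliber
#' independently of scanner magnification. Both are computed on the convex
#' hull by the rotating-calipers sweep: the maximum Feret diameter is the hull
#' diameter (largest antipodal vertex distance) and the minimum is the
#' smallest width over hull edge directions (the minimum width of a convex
#' polygon is always attained perpendicular to one of its edges).
#'
#' @param boundary Polygon (n x 2 matrix, pixel coordinates), >= 3
#'   non-collinear vertices.
#' @param calibration A [slide_calibration()]; diameters are returned in
#'   micrometers.
#' @return Named numeric vector `c(feret_min_um, feret_max_um)`.
#' @export
#' @examples
#' cal <- slide_calibration("S1", 100, 100, 1)
#' feret_diameters(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), cal)  # 1, sqrt(2)
feret_diameters <- function(boundary, calibration) {
  stopifnot(inherits(calibration, "slide_calibration"))
  boundary <- as_poly_matrix(boundary)
  h <- convex_hull_ccw(boundary)
  if (is.null(h))
    stop("degenerate hull: polygon vertices are collinear", call. = FALSE)
  n <- nrow(h)
  # twice the signed triangle area (a, b, c)
  tri2 <- function(a, b, cc)
    (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
  edist <- function(a, b) sqrt(sum((a - b)^2))
  nxt <- function(i) if (i == n) 1L else i + 1L
  j <- 2L
  min_width <- Inf
  max_diam <- 0
  for (i in seq_len(n)) {
    i2 <- nxt(i)
    # advance the caliper vertex j while it moves farther from edge (i, i2)
    repeat {
      j2 <- nxt(j)
      if (tri2(h[i, ], h[i2, ], h[j2, ]) > tri2(h[i, ], h[i2, ], h[j, ])) j <- j2
      else break
    }
    elen <- edist(h[i, ], h[i2, ])
    min_width <- min(min_width, abs(tri2(h[i, ], h[i2, ], h[j, ])) / elen)
    max_diam <- max(max_diam, edist(h[i, ], h[j, ]), edist(h[i2, ], h[j, ]))
  }
  mpp <- calibration$microns_per_pixel
  c(feret_min_um = min_width * mpp, feret_max_um = max_diam * mpp)
}
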