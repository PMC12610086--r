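# Internal planar-geometry utilities. All polygons are n x 2 numeric matrices
# of vertices in pixel coordinates, implicitly closed (first vertex not
# repeated). Origin top-left, y increasing downward, 0-based.

as_poly_matrix <- function(p, what = "polygon") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p))
    stop(what, " must be an n x 2 numeric matrix of vertices", call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop(what, " has non-finite vertices", call. = FALSE)
  unname(p)
}

# Signed shoelace area (positive for counter-clockwise vertex order in a
# y-up frame; callers use abs()).
poly_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

poly_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(p), 1)) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# Proper segment-intersection test between all non-adjacent edge pairs.
# O(n^2); annotation polygons are small (tens of vertices).
poly_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  orient <- function(px, py, qx, qy, rx, ry)
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      adjacent <- (k == i + 1L) || (i == 1L && k == n)
      if (adjacent) next
      o1 <- orient(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[k, 1], a[k, 2])
      o2 <- orient(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[k, 1], b[k, 2])
      o3 <- orient(a[k, 1], a[k, 2], b[k, 1], b[k, 2], a[i, 1], a[i, 2])
      o4 <- orient(a[k, 1], a[k, 2], b[k, 1], b[k, 2], b[i, 1], b[i, 2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0) return(FALSE)
    }
  }
  TRUE
}

# Point-in-polygon, vectorized over points (mgcv's C routine; boundary points
# count as inside).
points_in_poly <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
}

# TRUE for points falling inside any polygon of a list.
points_in_any <- function(pts, polys) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  hit <- rep(FALSE, nrow(pts))
  for (pl in polys) {
    idx <- which(!hit)
    if (!length(idx)) break
    hit[idx] <- points_in_poly(pts[idx, , drop = FALSE], pl)
  }
  hit
}

# Convex hull in counter-clockwise order (shoelace-positive), collinear
# vertices removed. Returns NULL when the hull is degenerate (< 3 distinct
# non-collinear points).
convex_hull_ccw <- function(p) {
  p <- unique(p)
  if (nrow(p) < 3L) return(NULL)
  h <- p[chull(p[, 1], p[, 2]), , drop = FALSE]
  if (nrow(h) < 3L) return(NULL)
  if (poly_signed_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  # drop collinear runs
  keep <- rep(TRUE, nrow(h))
  n <- nrow(h)
  for (i in seq_len(n)) {
    a <- h[if (i == 1L) n else i - 1L, ]
    b <- h[i, ]
    cc <- h[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    if (abs(cr) <= 1e-12 * max(1, abs(b[1] - a[1]), abs(cc[2] - a[2]))) keep[i] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  if (nrow(h) < 3L) return(NULL)
  h
}

# Minimum distance from each point to a polygon boundary (its closed edge
# set). Vectorized over points; loops over edges.
dist_to_poly_boundary <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    ex <- b[i, 1] - a[i, 1]; ey <- b[i, 2] - a[i, 2]
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      dx <- pts[, 1] - a[i, 1]; dy <- pts[, 2] - a[i, 2]
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1] - a[i, 1]) * ex + (pts[, 2] - a[i, 2]) * ey) / len2))
      dx <- pts[, 1] - (a[i, 1] + t * ex); dy <- pts[, 2] - (a[i, 2] + t * ey)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

poly_bbox <- function(polys) {
  if (is.matrix(polys)) polys <- list(polys)
  xs <- range(unlist(lapply(polys, function(p) range(p[, 1]))))
  ys <- range(unlist(lapply(polys, function(p) range(p[, 2]))))
  c(xmin = xs[1], ymin = ys[1], xmax = xs[2], ymax = ys[2])
}
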