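# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive and separate from the package's own algorithms.

# Ray-casting point-in-polygon, vectorized over points.
ray_cast_pip <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Feret diameters by projecting all vertices on a dense direction set: a
# 3600-angle grid enriched with the polygon's edge normals. The minimum width
# of a convex shape is attained exactly perpendicular to a hull edge, and the
# extent function is kinked (not smooth) there, so the plain grid alone
# carries O(grid step) error at the minimum; including the normals makes the
# brute force exact while keeping it a pure projection sweep.
feret_brute_force <- function(poly, mpp = 1, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  n <- nrow(poly)
  e <- poly[c(2:n, 1), , drop = FALSE] - poly
  th <- c(th, atan2(e[, 2], e[, 1]) + pi / 2)
  ext <- vapply(th, function(a) {
    proj <- poly[, 1] * cos(a) + poly[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  c(min(ext), max(ext)) * mpp
}

# Random simple (convex) polygon: points on a noisy ellipse, convex hull.
random_convex_poly <- function(n = 12, scale = 50) {
  pts <- cbind(rnorm(3 * n, 0, scale), rnorm(3 * n, 0, scale * runif(1, 0.2, 1)))
  ang <- runif(1, 0, pi)
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  pts <- pts %*% rot
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE] + matrix(runif(2, 100, 500), nrow = length(h),
                                  ncol = 2, byrow = TRUE)
}

# Minimal slide: 1000 x 1000 px at 1 um/px, square tumor and a disjoint
# square peritumoral patch of equal area.
toy_slide <- function(vessels = list(), mitoses = list(), necrosis = list(),
                      mpp = 1) {
  cal <- slide_calibration("toy", 1000, 1000, mpp)
  tumor <- rbind(c(100, 100), c(400, 100), c(400, 400), c(100, 400))
  peri <- rbind(c(500, 500), c(800, 500), c(800, 800), c(500, 800))
  annotated_slide(cal, region_set(list(tumor), list(peri)), vessels, mitoses,
                  necrosis)
}

# Small diamond-shaped vessel of a given pixel "radius" centered at (cx, cy).
diamond_vessel <- function(id, cx, cy, r = 2, invasive = FALSE) {
  vessel_annotation(id, rbind(c(cx - r, cy), c(cx, cy - r),
                              c(cx + r, cy), c(cx, cy + r)), invasive)
}

mitosis_at <- function(x, y, score = 1) mitosis_annotation(c(x, y), score)

# Cached default cohort pieces shared across expensive tests.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
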