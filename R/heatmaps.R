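# Segmented (categorical) and gradient (kernel-density) heatmaps.

heatmap_raster <- function(values, cell_size_um, kind, channel, origin_px) {
  structure(list(values = values, cell_size_um = cell_size_um,
                 kind = kind, channel = channel, origin_px = origin_px),
            class = "heatmap_raster")
}

#' @export
print.heatmap_raster <- function(x, ...) {
  cat(sprintf("<heatmap_raster> %s/%s: %d x %d cells of %g um\n",
              x$kind, x$channel, nrow(x$values), ncol(x$values),
              x$cell_size_um))
  invisible(x)
}

#' Segmented (categorical) heatmap
#'
#' Digitizes a count raster into intensity classes: each cell is mapped to the
#' index of the interval its value falls into, producing `length(breaks) + 1`
#' labels (0 = below the first break).
#'
#' @param grid A [bin_mitoses()] grid, a [gradient_heatmap()] raster, or a
#'   numeric matrix.
#' @param breaks Strictly ascending numeric break points.
#' @param channel Channel tag stored on the raster.
#' @return A `heatmap_raster` of kind `"segmented"` with integer labels.
#' @export
segmented_heatmap <- function(grid, breaks, channel = "mitoses") {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly ascending", call. = FALSE)
  if (inherits(grid, "mitosis_grid")) {
    vals <- grid$counts; cs <- grid$cell_size_um; org <- grid$origin
  } else if (inherits(grid, "heatmap_raster")) {
    vals <- grid$values; cs <- grid$cell_size_um; org <- grid$origin_px
    channel <- grid$channel
  } else {
    vals <- as.matrix(grid); cs <- NA_real_; org <- c(0, 0)
  }
  lab <- matrix(findInterval(vals, breaks), nrow(vals), ncol(vals))
  heatmap_raster(lab, cs, "segmented", channel, org)
}

#' Gradient (kernel-density) heatmap
#'
#' Isotropic Gaussian kernel density of annotated objects on a regular grid,
#' scaled so that the raster integrates to the number of points: summing
#' `values * cell_size_um^2` recovers the point count up to boundary losses
#' (within ~2% for interior patterns). Values are objects per square
#' micrometer.
#'
#' @param points n x 2 matrix of pixel coordinates (e.g. vessel centroids or
#'   mitosis locations).
#' @param calibration A [slide_calibration()].
#' @param bandwidth_um Gaussian kernel standard deviation in micrometers.
#' @param cell_size_um Output grid cell side in micrometers.
#' @param extent Optional `c(xmin, ymin, xmax, ymax)` in pixels; defaults to
#'   the full slide.
#' @param channel Channel tag stored on the raster.
#' @return A `heatmap_raster` of kind `"gradient"`.
#' @export
gradient_heatmap <- function(points, calibration, bandwidth_um = 250,
                             cell_size_um = 100, extent = NULL,
                             channel = "mitoses") {
  stopifnot(inherits(calibration, "slide_calibration"))
  if (!is.numeric(bandwidth_um) || bandwidth_um <= 0)
    stop("bandwidth_um must be positive", call. = FALSE)
  mpp <- calibration$microns_per_pixel
  if (is.null(extent))
    extent <- c(0, 0, calibration$width_px, calibration$height_px)
  cell_px <- cell_size_um / mpp
  nx <- max(1L, ceiling((extent[3] - extent[1]) / cell_px))
  ny <- max(1L, ceiling((extent[4] - extent[2]) / cell_px))
  vals <- matrix(0, nx, ny)
  if (!is.null(points) && nrow(points)) {
    # work in micrometers; kernel sd = bandwidth_um
    px_um <- (points[, 1] - extent[1]) * mpp
    py_um <- (points[, 2] - extent[2]) * mpp
    cx <- (seq_len(nx) - 0.5) * cell_size_um
    cy <- (seq_len(ny) - 0.5) * cell_size_um
    gx <- outer(cx, px_um, "-") / bandwidth_um
    gy <- outer(cy, py_um, "-") / bandwidth_um
    vals <- tcrossprod(dnorm(gx), dnorm(gy)) / bandwidth_um^2
    dim(vals) <- c(nx, ny)
  }
  heatmap_raster(vals, cell_size_um, "gradient", channel,
                 c(extent[1], extent[2]))
}

#' Export a heatmap raster as a CSV matrix
#'
#' @param raster A `heatmap_raster`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(raster, path) {
  stopifnot(inherits(raster, "heatmap_raster"))
  write.csv(raster$values, path, row.names = FALSE)
  invisible(path)
}

#' Render a heatmap over region outlines as a PNG
#'
#' Colors the raster through a fixed color ramp (sequential for gradient
#' rasters, discrete for segmented ones), upsamples each cell to a
#' `scale x scale` pixel block, and draws tumor/peritumoral outlines in black.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param slide An [annotated_slide()]; its regions provide the outlines.
#' @param raster A `heatmap_raster` lying within the slide bounds.
#' @param path Output PNG path.
#' @param scale Integer upsampling factor per raster cell.
#' @param colors Optional vector of R colors overriding the default ramp.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(slide, raster, path, scale = 4, colors = NULL) {
  stopifnot(inherits(slide, "annotated_slide"),
            inherits(raster, "heatmap_raster"))
  mpp <- slide$calibration$microns_per_pixel
  cell_px <- raster$cell_size_um / mpp
  nx <- nrow(raster$values); ny <- ncol(raster$values)
  x1 <- raster$origin_px[1] + nx * cell_px
  y1 <- raster$origin_px[2] + ny * cell_px
  if (raster$origin_px[1] < 0 || raster$origin_px[2] < 0 ||
      x1 > slide$calibration$width_px + cell_px ||
      y1 > slide$calibration$height_px + cell_px)
    stop("raster extent does not match the slide", call. = FALSE)
  v <- raster$values
  if (raster$kind == "segmented") {
    if (is.null(colors))
      colors <- c("#FFFFFF", "#FEE0D2", "#FB6A4A", "#A50F15", "#67000D")
    ncl <- max(v) + 1L
    pal <- rep(colors, length.out = max(ncl, 1L))
    idx <- v + 1L
  } else {
    if (is.null(colors)) colors <- c("#FFFFFF", "#FFF5C0", "#FD8D3C", "#800026")
    pal <- colorRampPalette(colors)(256)
    rng <- range(v)
    idx <- if (diff(rng) == 0) matrix(1L, nx, ny)
           else matrix(1L + as.integer(round(255 * (v - rng[1]) / diff(rng))), nx, ny)
  }
  rgbmat <- col2rgb(pal) / 255
  # image array: rows = y (downward), cols = x
  img <- array(0, dim = c(ny * scale, nx * scale, 3))
  for (ch in 1:3) {
    chan <- matrix(rgbmat[ch, idx], nx, ny)     # nx x ny
    up <- chan[rep(seq_len(nx), each = scale), rep(seq_len(ny), each = scale)]
    img[, , ch] <- t(up)
  }
  # rasterize region outlines
  px_per_unit <- scale / cell_px
  draw_poly <- function(p) {
    n <- nrow(p)
    a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
    for (i in seq_len(n)) {
      len <- sqrt(sum((b[i, ] - a[i, ])^2))
      k <- max(2L, ceiling(len * px_per_unit * 2))
      t <- seq(0, 1, length.out = k)
      xs <- a[i, 1] + t * (b[i, 1] - a[i, 1])
      ys <- a[i, 2] + t * (b[i, 2] - a[i, 2])
      cxp <- pmin(nx * scale, pmax(1L, ceiling((xs - raster$origin_px[1]) * px_per_unit)))
      cyp <- pmin(ny * scale, pmax(1L, ceiling((ys - raster$origin_px[2]) * px_per_unit)))
      img[cbind(cyp, cxp, 1)] <<- 0
      img[cbind(cyp, cxp, 2)] <<- 0
      img[cbind(cyp, cxp, 3)] <<- 0
    }
  }
  for (p in slide$regions$tumor) draw_poly(p)
  for (p in slide$regions$peritumoral) draw_poly(p)
  png::writePNG(img, path)
  invisible(path)
}
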