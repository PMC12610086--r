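# Seeded synthetic-slide generator: cohorts with the per-subtype statistical
# structure of the study (entropy, vessel counts, density, necrosis), plus
# fixture transforms.

#' Generator configuration
#'
#' @param seed Integer master seed; a fixed seed makes every generated byte
#'   reproducible.
#' @param slide_size_um Slide extent `c(width, height)` in micrometers.
#' @param microns_per_pixel Physical pixel size of the emulated scan.
#' @param grid_cell_um Default entropy-grid cell used for calibration.
#' @param n_slides_per_subtype Cohort size per subtype profile.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, slide_size_um = c(25000, 25000),
                             microns_per_pixel = 0.5, grid_cell_um = 150,
                             n_slides_per_subtype = 15L) {
  stopifnot(length(slide_size_um) == 2L, all(slide_size_um > 0),
            microns_per_pixel > 0, grid_cell_um > 0, n_slides_per_subtype >= 1)
  structure(list(seed = as.integer(seed),
                 slide_size_um = as.numeric(slide_size_um),
                 microns_per_pixel = as.numeric(microns_per_pixel),
                 grid_cell_um = as.numeric(grid_cell_um),
                 n_slides_per_subtype = as.integer(n_slides_per_subtype)),
            class = "generator_config")
}

#' Subtype generator profile
#'
#' Target statistics of one histologic subtype: entropy (dits), tumor vessel
#' density (%), the four compartment-by-caliber vessel counts (means and SDs),
#' the necrosis-fraction range, and the point-process shape parameters
#' (mitosis count, cluster seeds, cluster SD, clustering weight).
#'
#' @param subtype Subtype name.
#' @param entropy_mean,entropy_sd Target mitoses entropy in dits.
#' @param density_mean,density_sd Target relative vessel area density in
#'   percent.
#' @param n_small_center_mean,n_small_center_sd,n_small_periphery_mean,n_small_periphery_sd,n_large_center_mean,n_large_center_sd,n_large_periphery_mean,n_large_periphery_sd
#'   Vessel count targets per compartment and caliber.
#' @param necrosis_fraction_range Length-2 interval for the per-slide necrosis
#'   fraction draw.
#' @param clustering_weight Probability that a mitosis belongs to the
#'   perivascular clustered component (calibrated against the entropy target).
#' @param n_mitoses_mean Mean mitosis count per slide.
#' @param n_cluster_seeds Number of vessel-seeded clusters per slide.
#' @param cluster_sd_um Gaussian cluster spread in micrometers.
#' @param cluster_seed `"vessel"` to seed clusters at tumor-vessel centroids
#'   (perivascular hot spots) or `"uniform"` for vessel-independent cluster
#'   locations (lepidic-like singular clusters).
#' @param small_area_range,large_area_range Log-uniform vessel mask area
#'   ranges in square micrometers per caliber class.
#' @return An object of class `subtype_profile`.
#' @export
subtype_profile <- function(subtype,
                            entropy_mean, entropy_sd,
                            density_mean, density_sd,
                            n_small_center_mean, n_small_center_sd,
                            n_small_periphery_mean, n_small_periphery_sd,
                            n_large_center_mean, n_large_center_sd,
                            n_large_periphery_mean, n_large_periphery_sd,
                            necrosis_fraction_range = c(0, 0.05),
                            clustering_weight = 0,
                            n_mitoses_mean = 1000,
                            n_cluster_seeds = 5L,
                            cluster_sd_um = 150,
                            cluster_seed = c("vessel", "uniform"),
                            small_area_range = c(20, 300),
                            large_area_range = c(300, 5000)) {
  cluster_seed <- match.arg(cluster_seed)
  stopifnot(clustering_weight >= 0, clustering_weight <= 1,
            length(necrosis_fraction_range) == 2L,
            all(c(entropy_sd, density_sd, n_small_center_sd,
                  n_small_periphery_sd, n_large_center_sd,
                  n_large_periphery_sd) >= 0))
  structure(list(
    subtype = subtype,
    entropy_mean = entropy_mean, entropy_sd = entropy_sd,
    density_mean = density_mean, density_sd = density_sd,
    n_small_center_mean = n_small_center_mean,
    n_small_center_sd = n_small_center_sd,
    n_small_periphery_mean = n_small_periphery_mean,
    n_small_periphery_sd = n_small_periphery_sd,
    n_large_center_mean = n_large_center_mean,
    n_large_center_sd = n_large_center_sd,
    n_large_periphery_mean = n_large_periphery_mean,
    n_large_periphery_sd = n_large_periphery_sd,
    necrosis_fraction_range = as.numeric(necrosis_fraction_range),
    clustering_weight = clustering_weight,
    n_mitoses_mean = n_mitoses_mean,
    n_cluster_seeds = as.integer(n_cluster_seeds),
    cluster_sd_um = cluster_sd_um,
    cluster_seed = cluster_seed,
    small_area_range = as.numeric(small_area_range),
    large_area_range = as.numeric(large_area_range)),
    class = "subtype_profile")
}

#' Packaged subtype profiles
#'
#' Loads the five default subtype profiles (micropapillary, solid, papillary,
#' lepidic, acinar). Count, entropy and density targets are the published
#' cohort statistics; clustering weights, mitosis counts and vessel area
#' ranges are generator calibration constants documented in the YAML.
#'
#' @param path Optional alternative profile YAML.
#' @return Named list of [subtype_profile()] objects.
#' @export
default_subtype_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "subtype_profiles.yaml",
                        package = "mitovasc", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  out <- lapply(y$profiles, function(p) do.call(subtype_profile, p))
  names(out) <- vapply(out, `[[`, character(1), "subtype")
  out
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Count draw: rounded normal truncated at zero, with the pre-truncation
# location solved so the post-truncation mean equals `mean` (plain truncation
# would bias the realized mean upward). sd = 0 degenerates to round(mean).
rtrunc_count <- function(n, mean, sd) {
  if (sd == 0) return(rep(round(mean), n))
  f <- function(mu) mu * pnorm(mu / sd) + sd * dnorm(mu / sd) - mean
  mu <- if (mean <= 0) -6 * sd else
    uniroot(f, c(mean - 6 * sd, mean + sd), tol = 1e-9)$root
  pmax(0, round(rnorm(n, mu, sd)))
}

# Uniform rejection sampling of points inside a list of polygons. Batches are
# scaled by the observed acceptance rate; accepted chunks are collected in a
# list to avoid quadratic rbind growth.
runif_in_polys <- function(n, polys) {
  if (is.matrix(polys)) polys <- list(polys)
  if (n == 0) return(matrix(0, 0, 2))
  bb <- poly_bbox(polys)
  chunks <- list()
  got <- 0L
  acc <- 0.5
  while (got < n) {
    m <- min(500000L, max(ceiling((n - got) / max(acc, 0.01)), 100L))
    cand <- cbind(runif(m, bb["xmin"], bb["xmax"]),
                  runif(m, bb["ymin"], bb["ymax"]))
    hit <- cand[points_in_any(cand, polys), , drop = FALSE]
    acc <- max(nrow(hit) / m, 0.001)
    chunks[[length(chunks) + 1L]] <- hit
    got <- got + nrow(hit)
  }
  do.call(rbind, chunks)[seq_len(n), , drop = FALSE]
}

# Ellipse polygon with exact target area (vertices rescaled to cancel the
# inscribed-polygon area deficit), in the generator's micrometer frame.
ellipse_poly_um <- function(center, area_um2, aspect, angle, nv = 16L) {
  a <- sqrt(area_um2 * aspect / pi)
  b <- sqrt(area_um2 / (pi * aspect))
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  p <- cbind(x * cos(angle) - y * sin(angle), x * sin(angle) + y * cos(angle))
  p <- p * sqrt(area_um2 / poly_area(p))
  sweep(p, 2, center, "+")
}

#' Generate the tumor / peritumoral region pair
#'
#' A blob-like tumor polygon (harmonically perturbed ellipse) centered on the
#' slide and a surrounding annulus of equal area, split into four simple
#' quadrant polygons. Radial scaling makes the annulus area equal the tumor
#' area exactly (up to the deliberate 2% separation gap).
#'
#' @param config A [generator_config()].
#' @param seed Optional seed (defaults to the config seed).
#' @return A [region_set()] in pixel coordinates.
#' @export
generate_regions <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  with_optional_seed(seed, {
    mpp <- config$microns_per_pixel
    center <- config$slide_size_um / 2
    R <- 0.3 * min(config$slide_size_um)
    nv <- 96L
    th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    amp <- runif(4, 0, 0.03); ph <- runif(4, 0, 2 * pi)
    pert <- vapply(th, function(t) sum(amp * cos((2:5) * t + ph)), numeric(1))
    r <- R * (1 + pert)
    tumor_um <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
    inner_k <- 1.02
    outer_k <- sqrt(1 + inner_k^2)     # ring area == tumor area exactly
    rel <- sweep(tumor_um, 2, center)
    quads <- split(seq_len(nv), rep(1:4, each = nv / 4))
    peri_um <- lapply(quads, function(idx) {
      idx2 <- c(idx, if (max(idx) < nv) max(idx) + 1L else 1L)
      inner <- sweep(rel[idx2, , drop = FALSE] * inner_k, 2, center, "+")
      outer <- sweep(rel[rev(idx2), , drop = FALSE] * outer_k, 2, center, "+")
      rbind(inner, outer)
    })
    to_px <- function(p) round(p / mpp, 3)
    region_set(list(to_px(tumor_um)), lapply(peri_um, to_px))
  })
}

#' Generate vessel annotations for one subtype profile
#'
#' Per compartment-by-caliber cell, draws a count from the profile's
#' mean-calibrated truncated rounded normal, places vessel centroids uniformly
#' in the compartment, and emits ellipse-like polygons with mask areas drawn
#' log-uniformly from the profile's caliber area range. About 3% of vessels
#' carry the invasion flag.
#'
#' @param profile A [subtype_profile()].
#' @param regions A [region_set()] (pixel coordinates).
#' @param calibration A [slide_calibration()].
#' @param seed Optional seed.
#' @return List of [vessel_annotation()] objects.
#' @export
generate_vessels <- function(profile, regions, calibration, seed = NULL) {
  stopifnot(inherits(profile, "subtype_profile"),
            inherits(regions, "region_set"),
            inherits(calibration, "slide_calibration"))
  with_optional_seed(seed, {
    mpp <- calibration$microns_per_pixel
    specs <- list(
      list(cal = "small", comp = "center",
           n = rtrunc_count(1, profile$n_small_center_mean, profile$n_small_center_sd)),
      list(cal = "small", comp = "periphery",
           n = rtrunc_count(1, profile$n_small_periphery_mean, profile$n_small_periphery_sd)),
      list(cal = "large", comp = "center",
           n = rtrunc_count(1, profile$n_large_center_mean, profile$n_large_center_sd)),
      list(cal = "large", comp = "periphery",
           n = rtrunc_count(1, profile$n_large_periphery_mean, profile$n_large_periphery_sd)))
    vessels <- list()
    k <- 0L
    for (sp in specs) {
      n <- sp$n
      if (n == 0) next
      polys <- if (sp$comp == "center") regions$tumor else regions$peritumoral
      centers_px <- runif_in_polys(n, polys)
      rng <- if (sp$cal == "small") profile$small_area_range else profile$large_area_range
      # stay strictly inside the caliber interval after coordinate rounding
      lo <- log(rng[1] * 1.005); hi <- log(rng[2] * 0.9995)
      areas <- exp(runif(n, lo, hi))
      aspects <- runif(n, 1, 3)
      angles <- runif(n, 0, pi)
      invasive <- runif(n) < 0.029
      for (i in seq_len(n)) {
        k <- k + 1L
        p_um <- ellipse_poly_um(centers_px[i, ] * mpp, areas[i],
                                aspects[i], angles[i])
        vessels[[k]] <- vessel_annotation(
          sprintf("v%04d_%s_%s", k, sp$cal, substr(sp$comp, 1, 1)),
          round(p_um / mpp, 3), invasive[i])
      }
    }
    vessels
  })
}

#' Generate mitotic figures for one subtype profile
#'
#' Mixture point process inside the tumor: with probability
#' `1 - clustering_weight` a mitosis is uniform over the tumor region; with
#' probability `clustering_weight` it belongs to one of `n_cluster_seeds`
#' Gaussian clusters seeded at randomly chosen tumor-vessel centroids
#' (falling back to all vessels, or - with a warning - to the uniform
#' component when the slide has no vessels).
#'
#' @param profile A [subtype_profile()].
#' @param regions A [region_set()].
#' @param vessels List of [vessel_annotation()] (cluster seed candidates).
#' @param calibration A [slide_calibration()].
#' @param seed Optional seed.
#' @return List of [mitosis_annotation()] objects (score 1).
#' @export
generate_mitoses <- function(profile, regions, vessels, calibration,
                             seed = NULL) {
  stopifnot(inherits(profile, "subtype_profile"),
            inherits(regions, "region_set"),
            inherits(calibration, "slide_calibration"))
  with_optional_seed(seed, {
    mpp <- calibration$microns_per_pixel
    sdlog <- 0.25
    N <- max(1L, round(rlnorm(1, log(profile$n_mitoses_mean) - sdlog^2 / 2,
                              sdlog)))
    w <- profile$clustering_weight
    if (identical(profile$cluster_seed, "uniform")) vessels <- list()
    if (w > 0 && !length(vessels) &&
        !identical(profile$cluster_seed, "uniform")) {
      warning("no vessels to seed clusters; falling back to uniform mitoses")
      w <- 0
    }
    n_clustered <- rbinom(1, N, w)
    pts <- runif_in_polys(N - n_clustered, regions$tumor)
    if (n_clustered > 0) {
      cents <- if (length(vessels))
        do.call(rbind, lapply(vessels, function(v) poly_centroid(v$boundary)))
      else matrix(0, 0, 2)
      in_tumor <- points_in_any(cents, regions$tumor)
      # clusters must put mass inside the tumor: without an intratumoral
      # vessel centroid (vessel-independent mode, or vessel-poor slides whose
      # periphery-band centroids sit many kernel SDs outside the tumor),
      # seed at uniform tumor locations instead
      if (any(in_tumor)) {
        cand <- cents[in_tumor, , drop = FALSE]
        ns <- min(profile$n_cluster_seeds, nrow(cand))
        seeds <- cand[sample.int(nrow(cand), ns), , drop = FALSE]
      } else {
        ns <- profile$n_cluster_seeds
        seeds <- runif_in_polys(ns, regions$tumor)
      }
      sd_px <- profile$cluster_sd_um / mpp
      chunks <- list()
      got <- 0L
      acc <- 0.5    # acceptance-scaled batches: periphery-seeded clusters
      while (got < n_clustered) {   # put little mass inside the tumor
        m <- min(500000L,
                 max(ceiling((n_clustered - got) / max(acc, 0.01)), 50L))
        si <- sample.int(ns, m, replace = TRUE)
        cc <- seeds[si, , drop = FALSE] + matrix(rnorm(2 * m, 0, sd_px), ncol = 2)
        hit <- cc[points_in_any(cc, regions$tumor), , drop = FALSE]
        acc <- max(nrow(hit) / m, 0.001)
        chunks[[length(chunks) + 1L]] <- hit
        got <- got + nrow(hit)
      }
      pts <- rbind(pts, do.call(rbind, chunks)[seq_len(n_clustered), , drop = FALSE])
    }
    pts <- round(pts, 3)
    lapply(seq_len(nrow(pts)), function(i) mitosis_annotation(pts[i, ], 1))
  })
}

generate_necrosis <- function(profile, regions, calibration, seed = NULL) {
  with_optional_seed(seed, {
    nf <- runif(1, profile$necrosis_fraction_range[1],
                profile$necrosis_fraction_range[2])
    if (nf < 0.005) return(list(necrosis = list(), fraction = 0))
    tumor <- regions$tumor[[1]]
    a_t <- poly_area(tumor)
    ct <- poly_centroid(tumor)
    k <- 1L + (nf > 0.15) + (nf > 0.3)
    shares <- rep(nf * a_t / k, k)
    base_ang <- runif(1, 0, 2 * pi)
    offs <- 0.45 * sqrt(a_t / pi)
    polys <- lapply(seq_len(k), function(j) {
      ang <- base_ang + 2 * pi * (j - 1) / k
      cen <- ct + offs * c(cos(ang), sin(ang))
      r <- sqrt(shares[j] / pi)
      th <- seq(0, 2 * pi, length.out = 25L)[-25L]
      p <- cbind(cen[1] + r * cos(th), cen[2] + r * sin(th))
      round(p * sqrt(shares[j] / poly_area(p)) +
              rep(cen * (1 - sqrt(shares[j] / poly_area(p))), each = nrow(p)), 3)
    })
    frac <- sum(vapply(polys, poly_area, numeric(1))) / a_t
    list(necrosis = polys, fraction = frac)
  })
}

#' Generate one annotated slide from a subtype profile
#'
#' @param profile A [subtype_profile()].
#' @param config A [generator_config()].
#' @param slide_id Identifier for the slide.
#' @param seed Seed for this slide (defaults to the config seed).
#' @return An [annotated_slide()] that passes all package validation.
#' @export
generate_slide <- function(profile, config, slide_id = profile$subtype,
                           seed = config$seed) {
  stopifnot(inherits(profile, "subtype_profile"),
            inherits(config, "generator_config"))
  with_optional_seed(seed, {
    mpp <- config$microns_per_pixel
    cal <- slide_calibration(slide_id,
                             round(config$slide_size_um[1] / mpp),
                             round(config$slide_size_um[2] / mpp), mpp)
    regions <- generate_regions(config, seed = NULL)
    vessels <- generate_vessels(profile, regions, cal, seed = NULL)
    mitoses <- generate_mitoses(profile, regions, vessels, cal, seed = NULL)
    nec <- generate_necrosis(profile, regions, cal, seed = NULL)
    annotated_slide(cal, regions, vessels, mitoses, nec$necrosis,
                    profile$subtype)
  })
}

#' Generate a multi-subtype cohort
#'
#' Produces `config$n_slides_per_subtype` slides per profile with
#' deterministic per-slide seeds derived from the master seed. Optionally
#' writes each slide as GeoJSON plus a calibration sidecar, and a manifest
#' CSV.
#'
#' @param profiles List of [subtype_profile()] objects (e.g.
#'   [default_subtype_profiles()]).
#' @param config A [generator_config()].
#' @param out_dir Optional output directory for GeoJSON/sidecar/manifest
#'   files.
#' @return A list with `slides` (list of [annotated_slide()]) and `manifest`
#'   (data.frame: `slide_id`, `subtype`, `seed`, and file paths when
#'   `out_dir` is given).
#' @export
generate_cohort <- function(profiles, config, out_dir = NULL) {
  stopifnot(length(profiles) >= 1L, inherits(config, "generator_config"))
  if (inherits(profiles, "subtype_profile")) profiles <- list(profiles)
  slides <- list()
  rows <- list()
  idx <- 0L
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    for (i in seq_len(config$n_slides_per_subtype)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", prof$subtype, i)
      sseed <- (config$seed + 7919L * pi + i) %% .Machine$integer.max
      slides[[idx]] <- generate_slide(prof, config, sid, seed = sseed)
      rows[[idx]] <- data.frame(slide_id = sid, subtype = prof$subtype,
                                seed = sseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$annotation_path <- file.path(out_dir, paste0(manifest$slide_id, ".geojson"))
    manifest$calibration_path <- file.path(out_dir, paste0(manifest$slide_id, ".calibration.yaml"))
    for (i in seq_along(slides)) {
      write_slide(slides[[i]], manifest$annotation_path[i])
      write_calibration(slides[[i]]$calibration, manifest$calibration_path[i])
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(slides = slides, manifest = manifest)
}

#' Butterfly reflection of a tile
#'
#' Mirrors a tile horizontally and vertically into a 2x2 composite of twice
#' the height and width, symmetric about both center axes. Used as a boundary
#' artifact-free augmentation fixture.
#'
#' @param tile Non-empty numeric matrix (H x W).
#' @return A `2H x 2W` matrix.
#' @export
butterfly_reflection <- function(tile) {
  tile <- as.matrix(tile)
  if (!length(tile)) stop("empty tile", call. = FALSE)
  h <- tile[, rev(seq_len(ncol(tile))), drop = FALSE]
  rbind(cbind(tile, h),
        cbind(tile[rev(seq_len(nrow(tile))), , drop = FALSE],
              h[rev(seq_len(nrow(h))), , drop = FALSE]))
}

#' Score/label fixture reproducing given confusion counts
#'
#' Inverse construction for [threshold_sweep()]: generates per-candidate
#' detection and classification scores with labels such that sweeping at the
#' given thresholds reproduces `counts` exactly.
#'
#' @param counts A [confusion_counts()] object.
#' @param detection_thr,classification_thr Thresholds the fixture must
#'   reproduce the counts at (classification threshold must be positive when
#'   `tn + fn > 0`).
#' @param seed Optional seed for the score draws.
#' @return A list with `detection_scores`, `classification_scores`, `labels`.
#' @export
confusion_fixture <- function(counts, detection_thr = 0.3,
                              classification_thr = 0.65, seed = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (classification_thr <= 0 && (counts$tn + counts$fn) > 0)
    stop("cannot realize tn/fn at a zero classification threshold",
         call. = FALSE)
  with_optional_seed(seed, {
    pass_det <- function(n) runif(n, detection_thr, 1)
    pass_clf <- function(n) runif(n, classification_thr, 1)
    fail_clf <- function(n) runif(n, 0, classification_thr)
    n <- counts$tp + counts$fp + counts$tn + counts$fn
    det <- c(pass_det(counts$tp), pass_det(counts$fp),
             runif(counts$tn + counts$fn, 0, 1))
    clf <- c(pass_clf(counts$tp), pass_clf(counts$fp),
             fail_clf(counts$tn + counts$fn))
    lab <- c(rep(TRUE, counts$tp), rep(FALSE, counts$fp),
             rep(FALSE, counts$tn), rep(TRUE, counts$fn))
    ord <- if (n > 0) sample.int(n) else integer(0)
    list(detection_scores = det[ord], classification_scores = clf[ord],
         labels = lab[ord])
  })
}

#' Calibrate a profile's clustering weight against its entropy target
#'
#' Bisection on the clustering weight: generates small batches of slides at
#' candidate weights and matches the mean grid entropy (at the config's
#' default cell size) to the profile's entropy target. Expected entropy is
#' monotone decreasing in the weight.
#'
#' @param profile A [subtype_profile()].
#' @param config A [generator_config()].
#' @param reps Slides per candidate weight.
#' @param tol Acceptable |mean entropy - target| in dits.
#' @param max_iter Bisection iteration cap.
#' @return List with the calibrated `clustering_weight` and the `achieved`
#'   mean entropy.
#' @export
calibrate_clustering_weight <- function(profile, config, reps = 12L,
                                        tol = 0.1, max_iter = 12L) {
  mean_entropy <- function(w) {
    p <- profile; p$clustering_weight <- w
    mean(vapply(seq_len(reps), function(i) {
      s <- generate_slide(p, config, "cal", seed = config$seed + 31L * i)
      mitoses_entropy(bin_mitoses(s, config$grid_cell_um))
    }, numeric(1)))
  }
  lo <- 0; hi <- 1
  e_lo <- mean_entropy(lo)
  if (e_lo <= profile$entropy_mean + tol)
    return(list(clustering_weight = lo, achieved = e_lo))
  e_hi <- mean_entropy(hi)
  if (e_hi >= profile$entropy_mean - tol)
    return(list(clustering_weight = hi, achieved = e_hi))
  w <- 0.5; e <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- (lo + hi) / 2
    e <- mean_entropy(w)
    if (abs(e - profile$entropy_mean) <= tol) break
    if (e > profile$entropy_mean) lo <- w else hi <- w
  }
  list(clustering_weight = w, achieved = e)
}
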