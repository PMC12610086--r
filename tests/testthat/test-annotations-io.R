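test_that("calibration and annotation constructors enforce their invariants", {
  expect_error(slide_calibration("s", 0, 10, 1), "positive integers")
  expect_error(slide_calibration("s", 10, 10, 0), "microns_per_pixel")
  expect_error(mitosis_annotation(c(1, 2), 1.5), "\\[0, 1\\]")
  expect_error(vessel_annotation("v", rbind(c(0, 0), c(1, 1))), ">= 3 vertices")
  # self-intersecting polygon with nonzero shoelace area
  bow <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, -5))
  expect_error(vessel_annotation("v", bow), "self-intersecting")
  expect_error(region_set(list(bow), list(bow + 100)), "self-intersecting")
  # out-of-bounds geometry is rejected at the slide level
  cal <- slide_calibration("s", 100, 100, 1)
  sq <- rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50))
  expect_error(
    annotated_slide(cal, region_set(list(sq), list(sq + 200)), list(), list()),
    "outside slide bounds")
})

test_that("GeoJSON write/read round trip is the identity on valid slides", {
  slide <- toy_slide(
    vessels = list(diamond_vessel("v1", 200, 200, 5),
                   diamond_vessel("v2", 300.25, 210.125, 3, invasive = TRUE)),
    mitoses = list(mitosis_at(150.5, 160.125, 0.8), mitosis_at(210, 220),
                   mitosis_at(390.875, 110)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_slide(slide, path)
  back <- read_slide(path, slide$calibration)
  expect_length(back$regions$tumor, 1)
  expect_length(back$vessels, 2)
  expect_length(back$mitoses, 3)
  # coordinates reproduced bit-exactly (storage precision <= 3 decimals)
  expect_identical(back$regions$tumor[[1]], slide$regions$tumor[[1]])
  for (i in 1:2)
    expect_identical(back$vessels[[i]]$boundary, slide$vessels[[i]]$boundary)
  expect_identical(back$vessels[[2]]$invasive, TRUE)
  for (i in 1:3) {
    expect_identical(back$mitoses[[i]]$location, slide$mitoses[[i]]$location)
    expect_identical(back$mitoses[[i]]$score, slide$mitoses[[i]]$score)
  }
})

test_that("write_slide emits one feature per object; empty slides hold only regions", {
  empty <- toy_slide()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_slide(empty, path)
  fc <- jsonlite::read_json(path)
  expect_length(fc$features, 2)   # tumor + peritumoral only
  vessels <- lapply(1:17, function(i)
    diamond_vessel(paste0("v", i), 110 + 10 * i, 200, 2))
  write_slide(toy_slide(vessels = vessels), path)
  fc <- jsonlite::read_json(path)
  cls <- vapply(fc$features, function(f) f$properties$class, character(1))
  expect_identical(sum(cls == "vessel"), 17L)
})

test_that("unknown feature classes and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(list(type = "Feature",
                         geometry = list(type = "Point", coordinates = c(1, 2)),
                         properties = list(class = "stroma", id = "x1")))),
    auto_unbox = TRUE), path)
  cal <- slide_calibration("s", 100, 100, 1)
  expect_error(read_slide(path, cal), "unknown feature class")
  writeLines("{\"type\": \"Polygon\"}", path)
  expect_error(read_slide(path, cal), "FeatureCollection")
})

test_that("region balance reports the peritumoral / tumor area ratio", {
  sq <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                  c(x0 + s, y0 + s), c(x0, y0 + s))
  rs <- region_set(list(sq(0, 0, 100)), list(sq(200, 200, 100)))
  bal <- check_region_balance(rs, tolerance = 0.1)
  expect_equal(bal$ratio, 1.0)
  expect_true(bal$pass)
  # peritumoral twice the tumor area: ratio 2, fail
  rs2 <- region_set(list(sq(0, 0, 100)),
                    list(sq(200, 200, 100), sq(350, 350, 100)))
  bal2 <- check_region_balance(rs2, tolerance = 0.1)
  expect_equal(bal2$ratio, 2.0)
  expect_false(bal2$pass)
  # scale invariance: multiplying all coordinates by k leaves ratio unchanged
  k <- 7.3
  rs3 <- region_set(list(sq(0, 0, 100) * k), list(sq(200, 200, 100) * k))
  expect_equal(check_region_balance(rs3)$ratio, bal$ratio)
  # ratio on a generated slide matches the direct polygon-area sums
  cfg <- generator_config(seed = 5)
  regs <- generate_regions(cfg)
  shoelace <- function(p) {
    n <- nrow(p); j <- c(n, seq_len(n - 1))
    abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
  }
  bal4 <- check_region_balance(regs)
  expect_equal(bal4$ratio,
               sum(vapply(regs$peritumoral, shoelace, numeric(1))) /
                 sum(vapply(regs$tumor, shoelace, numeric(1))))
})

test_that("sliding window covers the slide with the requested overlap", {
  cal <- slide_calibration("s", 1024, 1024, 1)
  tiles <- sliding_window(cal, 512, 0)
  expect_identical(nrow(tiles), 4L)
  # degenerate: tile size equals the slide
  cal2 <- slide_calibration("s", 512, 512, 1)
  expect_identical(nrow(sliding_window(cal2, 512, 0.3)), 1L)
  expect_error(sliding_window(cal, 512, 1), "overlap_fraction")
  # rasterized coverage oracle: every pixel covered at least once
  cal3 <- slide_calibration("s", 300, 200, 1)
  tiles3 <- sliding_window(cal3, 128, 0.1)
  cover <- matrix(0L, 300, 200)
  for (i in seq_len(nrow(tiles3))) {
    xs <- (tiles3$x0[i] + 1):tiles3$x1[i]
    ys <- (tiles3$y0[i] + 1):tiles3$y1[i]
    cover[xs, ys] <- cover[xs, ys] + 1L
  }
  expect_true(all(cover >= 1L))
  # adjacent tiles share ~10% of the tile side
  xs <- sort(unique(tiles3$x0))
  expect_true(all(abs((xs[-1] - xs[-length(xs)]) - round(128 * 0.9)) <= 1 |
                    xs[-1] == max(xs)))
})
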