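test_that("mitoses are binned by floor division with boundary ties upward", {
  # toy tumor spans (100,100)-(400,400); cell 50 um at 1 um/px = 50 px
  slide <- toy_slide(mitoses = list(mitosis_at(110, 110), mitosis_at(120, 115),
                                    mitosis_at(130, 140),      # same first cell
                                    mitosis_at(150, 100),      # x boundary tie
                                    mitosis_at(600, 600)))     # outside tumor
  g <- bin_mitoses(slide, cell_size_um = 50)
  expect_identical(g$n_mitoses_tumor, 4L)
  expect_identical(g$counts[1, 1], 3L)
  # the boundary point goes to the higher-index cell (floor rule)
  expect_identical(g$counts[2, 1], 1L)
  # grid total equals a brute-force membership count
  pts <- do.call(rbind, lapply(slide$mitoses, function(m) m$location))
  expect_identical(sum(g$counts),
                   sum(ray_cast_pip(pts, slide$regions$tumor[[1]])))
})

test_that("a cell larger than the tumor bounding box yields a single-cell grid", {
  slide <- toy_slide(mitoses = list(mitosis_at(200, 200), mitosis_at(350, 390)))
  g <- bin_mitoses(slide, cell_size_um = 5000)
  expect_identical(dim(g$counts), c(1L, 1L))
  expect_identical(g$counts[1, 1], 2L)
  expect_equal(mitoses_entropy(g), 0)
})

test_that("entropy matches its closed forms in dits", {
  # all mitoses in one cell -> 0 dits
  slide1 <- toy_slide(mitoses = lapply(1:7, function(i) mitosis_at(110, 110)))
  expect_equal(mitoses_entropy(bin_mitoses(slide1, 50)), 0)
  # uniform over k occupied cells -> log10(k), exactly
  cells10 <- lapply(0:9, function(i) mitosis_at(105 + 30 * i, 110))
  g10 <- bin_mitoses(toy_slide(mitoses = cells10), 30)
  expect_equal(mitoses_entropy(g10), 1.0)
  cells100 <- do.call(c, lapply(0:9, function(i) lapply(0:9, function(j)
    mitosis_at(102 + 30 * i, 102 + 30 * j))))
  g100 <- bin_mitoses(toy_slide(mitoses = cells100), 30)
  expect_equal(mitoses_entropy(g100), 2.0)
  # empty slide convention
  expect_equal(mitoses_entropy(bin_mitoses(toy_slide(), 50)), 0)
})

test_that("entropy is bounded, permutation-invariant and scales as log10 k", {
  withr::local_seed(44)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    pts <- cbind(runif(n, 101, 399), runif(n, 101, 399))
    slide <- toy_slide(mitoses = lapply(seq_len(n), function(i)
      mitosis_at(pts[i, 1], pts[i, 2])))
    g <- bin_mitoses(slide, 50)
    h <- mitoses_entropy(g)
    expect_gte(h, 0)
    expect_lte(h, log10(sum(g$tumor_mask)) + 1e-12)
    # shuffling the points leaves the entropy unchanged
    ord <- sample(n)
    g2 <- bin_mitoses(toy_slide(mitoses = lapply(ord, function(i)
      mitosis_at(pts[i, 1], pts[i, 2]))), 50)
    expect_equal(mitoses_entropy(g2), h)
  }
})

test_that("hot spots are high-count cells and never single mitoses", {
  slide <- toy_slide(mitoses = c(lapply(1:5, function(i) mitosis_at(110, 110)),
                                 list(mitosis_at(210, 210))))
  hs <- detect_hotspots(bin_mitoses(slide, 50), 0.95)
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$count, 5L)
  # all-singleton cells: no hot spots despite any quantile
  singles <- lapply(0:9, function(i) mitosis_at(105 + 30 * i, 110))
  expect_identical(nrow(detect_hotspots(bin_mitoses(toy_slide(mitoses = singles), 30),
                                        0.5)), 0L)
  expect_identical(nrow(detect_hotspots(bin_mitoses(toy_slide(), 50), 0.95)), 0L)
  # brute-force threshold scan oracle
  withr::local_seed(55)
  n <- 300
  pts <- cbind(runif(n, 101, 399), runif(n, 101, 399))
  g <- bin_mitoses(toy_slide(mitoses = lapply(seq_len(n), function(i)
    mitosis_at(pts[i, 1], pts[i, 2]))), 40)
  hs <- detect_hotspots(g, 0.9)
  thr <- max(2, quantile(g$counts[g$counts > 0], 0.9, type = 7))
  want <- sum(g$counts >= thr)
  expect_identical(nrow(hs), as.integer(want))
  expect_true(all(g$counts[cbind(hs$ix, hs$iy)] == hs$count))
})

test_that("perivascular fraction agrees with brute-force distances and is monotone", {
  v <- diamond_vessel("v", 250, 250, 10)
  slide <- toy_slide(vessels = list(v),
                     mitoses = list(mitosis_at(260, 250),   # on the boundary
                                    mitosis_at(340, 250),   # 80 px away
                                    mitosis_at(250, 250),   # inside the vessel
                                    mitosis_at(110, 390)))  # far corner
  expect_equal(perivascular_fraction(slide, 50), 2 / 4)
  expect_equal(perivascular_fraction(toy_slide(mitoses = list(mitosis_at(200, 200)))),
               0)   # no vessels
  # monotone non-decreasing in the radius
  radii <- c(10, 50, 90, 150, 300)
  fr <- vapply(radii, function(r) perivascular_fraction(slide, r), numeric(1))
  expect_true(all(diff(fr) >= 0))
  # brute-force all-pairs point-to-segment oracle
  withr::local_seed(66)
  vs <- lapply(1:5, function(i)
    diamond_vessel(paste0("v", i), runif(1, 150, 350), runif(1, 150, 350), 8))
  n <- 100
  pts <- cbind(runif(n, 101, 399), runif(n, 101, 399))
  slide2 <- toy_slide(vessels = vs, mitoses = lapply(seq_len(n), function(i)
    mitosis_at(pts[i, 1], pts[i, 2])))
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab * ab)))
    sqrt(sum((p - a - t * ab)^2))
  }
  radius <- 40
  near <- vapply(seq_len(n), function(i) {
    dmin <- Inf
    for (v in vs) {
      bd <- v$boundary
      for (k in seq_len(nrow(bd))) {
        a <- bd[k, ]; b <- bd[if (k == nrow(bd)) 1 else k + 1, ]
        dmin <- min(dmin, seg_dist(pts[i, ], a, b))
      }
    }
    dmin <= radius
  }, logical(1))
  expect_equal(perivascular_fraction(slide2, radius), mean(near))
})
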