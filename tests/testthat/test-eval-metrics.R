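test_that("confusion metrics reproduce the published detector evaluation rows", {
  after <- confusion_counts(182, 24, 620, 26, "combined")
  m <- confusion_metrics(after)
  expect_equal(round(m$specificity, 2), 0.96)
  muscle <- confusion_metrics(confusion_counts(193, 240, 19, 15,
                                               "muscle/fibroblast nucleus"))
  expect_equal(round(muscle$specificity, 2), 0.07)
  perfect <- confusion_metrics(confusion_counts(10, 0, 10, 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  precision = 1, f1 = 1))
  expect_error(confusion_metrics(confusion_counts(0, 5, 5, 0)),
               "sensitivity")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("F1 is the harmonic mean and consistent with confusion counts", {
  expect_equal(round(f1_from_pr(0.89, 0.83), 2), 0.86)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_error(f1_from_pr(0, 0), "positive")
  withr::local_seed(10)
  for (rep in 1:20) {
    cc <- confusion_counts(sample(1:200, 1), sample(0:100, 1),
                           sample(0:300, 1) + 1L, sample(0:50, 1))
    m <- confusion_metrics(cc)
    expect_equal(m$f1, f1_from_pr(m$precision, m$sensitivity))
  }
})

test_that("hard-negative rows aggregate by summing FP and TN", {
  after <- list(confusion_counts(182, 2, 297, 26, "ink"),
                confusion_counts(182, 1, 258, 26, "muscle"),
                confusion_counts(182, 21, 65, 26, "chromatin"))
  comb <- combine_negative_classes(after)
  expect_identical(comb$fp, 24L)
  expect_identical(comb$tn, 620L)
  expect_identical(comb$tp, 182L)
  before <- list(confusion_counts(193, 5, 294, 15, "ink"),
                 confusion_counts(193, 240, 19, 15, "muscle"),
                 confusion_counts(193, 80, 6, 15, "chromatin"))
  comb2 <- combine_negative_classes(before)
  expect_identical(comb2$fp, 325L)
  expect_identical(comb2$tn, 319L)
  # combined specificity equals sum(tn)/(sum(tn)+sum(fp)) exactly
  expect_equal(confusion_metrics(comb2)$specificity, 319 / (319 + 325))
  # a single row combines to itself
  one <- combine_negative_classes(after[1])
  expect_identical(one$fp, 2L)
  expect_error(combine_negative_classes(list(after[[1]],
                                             confusion_counts(9, 9, 9, 9))),
               "positive set")
})

test_that("IoU and Dice follow their algebraic relationship", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(overlap_metrics(a, a), c(iou = 1, dice = 1))
  b <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(overlap_metrics(a, b), c(iou = 0, dice = 0))
  e <- matrix(FALSE, 2, 2)
  expect_equal(overlap_metrics(e, e), c(iou = 1, dice = 1))
  expect_error(overlap_metrics(a, matrix(TRUE, 3, 3)), "shape")
  withr::local_seed(12)
  for (rep in 1:20) {
    x <- matrix(runif(100) < 0.4, 10)
    y <- matrix(runif(100) < 0.4, 10)
    m <- overlap_metrics(x, y)
    expect_equal(unname(m["dice"]), unname(2 * m["iou"] / (1 + m["iou"])))
    expect_lte(m["iou"], m["dice"])
  }
})

test_that("ROC AUC equals the Mann-Whitney rank statistic", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both label classes")
  withr::local_seed(13)
  n1 <- 60; n0 <- 80
  scores <- c(rnorm(n1, 1), rnorm(n0))
  labels <- c(rep(TRUE, n1), rep(FALSE, n0))
  u <- wilcox.test(scores[labels], scores[!labels])$statistic
  expect_equal(roc_auc(scores, labels), unname(u) / (n1 * n0))
  # invariance under strictly monotone transform
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  # independent labels: AUC near 1/2
  big <- rnorm(4000)
  expect_equal(roc_auc(big, rep(c(TRUE, FALSE), 2000)), 0.5, tolerance = 0.05)
})

test_that("the two-stage threshold sweep counts match a brute-force filter", {
  det <- c(0.1, 0.2, 0.25)
  expect_identical(threshold_sweep(det, c(0.9, 0.9, 0.9),
                                   c(TRUE, TRUE, FALSE))$tp, 0L)
  all_pos <- threshold_sweep(c(0.5, 0.5), c(0.5, 0.5), c(TRUE, FALSE), 0, 0)
  expect_identical(all_pos$tp, 1L)
  expect_identical(all_pos$fp, 1L)
  withr::local_seed(14)
  n <- 500
  d <- runif(n); cscore <- runif(n); lab <- runif(n) < 0.3
  sw <- threshold_sweep(d, cscore, lab, 0.3, 0.65)
  pos <- d >= 0.3 & cscore >= 0.65
  expect_identical(sw$tp, sum(pos & lab))
  expect_identical(sw$fp, sum(pos & !lab))
  expect_identical(sw$tn, sum(!pos & !lab))
  expect_identical(sw$fn, sum(!pos & lab))
})

test_that("confusion fixtures invert threshold_sweep exactly", {
  t2 <- confusion_counts(182, 24, 620, 26)
  fx <- confusion_fixture(t2, 0.3, 0.65, seed = 99)
  got <- threshold_sweep(fx$detection_scores, fx$classification_scores,
                         fx$labels, 0.3, 0.65)
  expect_identical(got$tp, 182L); expect_identical(got$fp, 24L)
  expect_identical(got$tn, 620L); expect_identical(got$fn, 26L)
  # zero counts -> empty sequences
  fx0 <- confusion_fixture(confusion_counts(0, 0, 0, 0), seed = 1)
  expect_length(fx0$labels, 0)
  # random tables round-trip exactly
  withr::local_seed(15)
  for (rep in 1:100) {
    cc <- confusion_counts(sample(0:300, 1), sample(0:300, 1),
                           sample(0:300, 1), sample(0:300, 1))
    thr_d <- runif(1, 0.05, 0.95); thr_c <- runif(1, 0.05, 0.95)
    fx <- confusion_fixture(cc, thr_d, thr_c, seed = rep)
    got <- threshold_sweep(fx$detection_scores, fx$classification_scores,
                           fx$labels, thr_d, thr_c)
    expect_identical(unclass(got)[c("tp", "fp", "tn", "fn")],
                     unclass(cc)[c("tp", "fp", "tn", "fn")])
  }
})

test_that("confusion tables survive a CSV round trip", {
  rows <- list(confusion_counts(182, 2, 297, 26, "ink"),
               confusion_counts(182, 21, 65, 26, "chromatin"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(rows, path)
  back <- read_confusion_csv(path)
  expect_identical(back, rows)
})
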