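# Metrics checked against exhaustive per-pixel tallies.

brute_confusion <- function(y, p) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

test_that("confusion counts match a per-pixel brute force", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_identical(confusion_counts(y, y), list(TP = 3L, FP = 0L, TN = 5L, FN = 0L))
  cc <- confusion_counts(y, 1 - y)
  expect_identical(cc$TP, 0L); expect_identical(cc$TN, 0L)
  set.seed(41)
  for (rep_ in 1:10) {
    yt <- rbinom(16, 1, 0.5); yp <- rbinom(16, 1, 0.5)
    expect_identical(lapply(confusion_counts(yt, yp), as.numeric),
                     lapply(brute_confusion(yt, yp), as.numeric))
  }
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("overlap metrics: identity, known split, and the miou/dsc identity", {
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(overlap_metrics(m, m), list(dsc = 1, miou = 1))
  # |Y| = |Yhat| = 4, intersection 2
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p <- c(1, 1, 0, 0, 1, 1, 0, 0)
  ov <- overlap_metrics(y, p)
  expect_equal(ov$dsc, 0.5)
  expect_equal(ov$miou, 1 / 3)
  set.seed(42)
  for (rep_ in 1:20) {
    yt <- rbinom(50, 1, runif(1, 0.1, 0.9))
    yp <- rbinom(50, 1, runif(1, 0.1, 0.9))
    ov <- overlap_metrics(yt, yp)
    expect_equal(ov$miou, ov$dsc / (2 - ov$dsc))
    expect_lte(ov$miou, ov$dsc)
    if (!ov$dsc %in% c(0, 1)) expect_lt(ov$miou, ov$dsc)
  }
  expect_equal(overlap_metrics(rep(0, 9), rep(0, 9)), list(dsc = 1, miou = 1))
})

test_that("rate metrics follow the confusion-count formulas", {
  r <- rate_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(r$pr, 0.75); expect_equal(r$re, 0.75)
  expect_equal(r$f1, 0.75); expect_equal(r$sp, 5 / 6)
  perfect <- rate_metrics(list(TP = 7, FP = 0, TN = 3, FN = 0))
  expect_equal(unlist(perfect[c("pr", "re", "f1")]), c(pr = 1, re = 1, f1 = 1))
  r0 <- suppressWarnings(rate_metrics(list(TP = 0, FP = 0, TN = 5, FN = 2)))
  expect_equal(r0$pr, 0)
  # TP = 0 with TP+FP > 0: precision 0 without warning, F1 denominator warns
  expect_warning(r1 <- rate_metrics(list(TP = 0, FP = 3, TN = 2, FN = 1)),
                 "zero denominator")
  expect_equal(r1$pr, 0)
})

test_that("evaluate_set aggregates per image and over pooled pixels", {
  m1 <- matrix(rbinom(64, 1, 0.5), 8, 8)
  rep1 <- evaluate_set(list(m1 * 0.9 + 0.05), list(m1))
  expect_true(all(abs(as.matrix(rep1[, -1]) - 1) < 1e-12))

  # dsc 1.0 and 0.5 -> per-image mean 0.75
  y2 <- matrix(c(rep(1, 4), rep(0, 60)), 8, 8)
  p2 <- matrix(c(1, 1, 0, 0, 1, 1, rep(0, 58)), 8, 8)
  rep2 <- evaluate_set(list(y2 * 1.0, p2 * 1.0), list(y2, y2))
  expect_equal(rep2$dsc[rep2$aggregation == "per_image_mean"], 0.75)

  set.seed(43)
  preds <- lapply(1:5, function(i) matrix(runif(36), 6, 6))
  truths <- lapply(1:5, function(i) matrix(rbinom(36, 1, 0.4), 6, 6))
  rp <- evaluate_set(preds, truths)
  pooled <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:5)
    pooled <- Map(`+`, pooled,
                  brute_confusion(truths[[i]], (preds[[i]] >= 0.5) * 1))
  g <- rp[rp$aggregation == "global_pixels", ]
  expect_equal(g$pr, pooled$TP / (pooled$TP + pooled$FP))
  expect_equal(g$re, pooled$TP / (pooled$TP + pooled$FN))
  expect_equal(g$sp, pooled$TN / (pooled$TN + pooled$FP))
  # pooled F1 equals pooled dice: both are 2TP / (2TP + FP + FN)
  expect_equal(g$f1, g$dsc)
  expect_equal(g$dsc, 2 * pooled$TP / (2 * pooled$TP + pooled$FP + pooled$FN))
  expect_error(evaluate_set(list(), list()), "empty")
})

test_that("metrics are invariant to a simultaneous spatial permutation", {
  set.seed(44)
  y <- matrix(rbinom(49, 1, 0.4), 7, 7)
  p <- matrix(rbinom(49, 1, 0.5), 7, 7)
  perm <- sample(49)
  before <- c(overlap_metrics(y, p),
              rate_metrics(confusion_counts(y, p)))
  after <- c(overlap_metrics(y[perm], p[perm]),
             rate_metrics(confusion_counts(y[perm], p[perm])))
  expect_equal(before, after)
})

test_that("metrics JSON report rounds percentages to two decimals", {
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  p <- matrix(runif(64), 8, 8)
  rp <- evaluate_set(list(p), list(y))
  path <- tempfile(fileext = ".json")
  write_metrics_json(rp, path)
  j <- jsonlite::read_json(path)
  expect_named(j, c("per_image_mean", "global_pixels"))
  expect_equal(j$global_pixels$dsc,
               round(100 * rp$dsc[rp$aggregation == "global_pixels"], 2))
})
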