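test_that("confusion counts match a per-pixel loop oracle", {
  set.seed(20)
  pred <- matrix(rbinom(2500, 1, 0.4), 50, 50)
  truth <- matrix(rbinom(2500, 1, 0.3), 50, 50)
  got <- confusion(pred, truth)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:50) for (j in 1:50) {
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
    if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1L
    if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
    if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
  }
  expect_identical(unclass(got), list(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_identical(got$tp + got$tn + got$fp + got$fn, 2500L)

  same <- confusion(truth, truth)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  flip <- confusion(1 - truth, truth)
  expect_identical(c(flip$tp, flip$tn), c(0L, 0L))
  expect_error(confusion(pred[1:10, ], truth), "shapes differ")
  expect_error(confusion(pred * 2, truth), "binary")
})

test_that("the eight metrics follow their defining ratios", {
  r <- report(confusion(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 1, 0, 0), 2)))
  for (m in c("se", "sp", "acc", "precision", "dsc", "jsi"))
    expect_identical(r[[m]], 1)
  expect_identical(c(r$fpr, r$fnr), c(0, 0))

  counts <- structure(list(tp = 80L, tn = 880L, fp = 20L, fn = 20L),
                      class = "confusion_counts")
  r <- report(counts)
  expect_equal(r$se, 0.8, tolerance = 1e-12)
  expect_equal(r$precision, 0.8, tolerance = 1e-12)
  expect_equal(r$dsc, 2 * 80 / (20 + 160 + 20), tolerance = 1e-12)
  expect_equal(r$jsi, 0.8 / 1.2, tolerance = 1e-12)
  expect_equal(r$acc, 0.96, tolerance = 1e-12)
  expect_equal(r$fpr, 1 - r$sp, tolerance = 1e-15)
  expect_equal(r$fnr, 1 - r$se, tolerance = 1e-15)
  expect_error(report(structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L),
                                class = "confusion_counts")), "all-zero")
})

test_that("zero-denominator metrics are flagged NaN, never silent zeros", {
  counts <- structure(list(tp = 0L, tn = 90L, fp = 0L, fn = 0L),
                      class = "confusion_counts")
  r <- report(counts)
  expect_true(is.nan(r$se))
  expect_true(is.nan(r$precision))
  expect_true(all(c("se", "precision", "fnr", "dsc", "jsi") %in% r$undefined))
  expect_identical(r$acc, 1)
})

test_that("Jaccard from Dice and its algebraic inverse", {
  expect_identical(jsi_from_dsc(1), 1)
  expect_identical(jsi_from_dsc(0), 0)
  expect_equal(round(100 * jsi_from_dsc(0.929), 2), 86.74)
  expect_equal(round(100 * jsi_from_dsc(0.9731), 2), 94.76)
  g <- seq(0, 1, by = 0.01)
  j <- jsi_from_dsc(g)
  expect_equal(2 * j / (1 + j), g, tolerance = 1e-12)
  expect_error(jsi_from_dsc(1.2), "lie in")
})

test_that("aggregation modes differ on disjoint unit sizes", {
  r1 <- report(structure(list(tp = 9L, tn = 90L, fp = 1L, fn = 0L),
                         class = "confusion_counts"), id = "small")
  r2 <- report(structure(list(tp = 500L, tn = 8000L, fp = 800L, fn = 700L),
                         class = "confusion_counts"), id = "large")
  expect_identical(aggregate_reports(list(r1), "mean_of_metrics")$dsc, r1$dsc)
  expect_identical(aggregate_reports(list(r1), "pooled_counts")$dsc, r1$dsc)
  mm <- aggregate_reports(list(r1, r2), "mean_of_metrics")
  pc <- aggregate_reports(list(r1, r2), "pooled_counts")
  expect_equal(mm$dsc, mean(c(r1$dsc, r2$dsc)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mm$dsc, pc$dsc)))
  expect_error(aggregate_reports(list()), "no reports")
})

test_that("adding a true positive never hurts", {
  set.seed(4)
  for (i in 1:50) {
    c0 <- as.list(rpois(4, 30) + 1L)
    names(c0) <- c("tp", "tn", "fp", "fn")
    r0 <- report(structure(c0, class = "confusion_counts"))
    c1 <- c0; c1$tp <- c1$tp + 1L
    r1 <- report(structure(c1, class = "confusion_counts"))
    for (m in c("se", "precision", "dsc", "jsi", "acc"))
      expect_gte(r1[[m]], r0[[m]])
  }
})

test_that("the CSV layout uses percent columns for the first six metrics", {
  r <- report(structure(list(tp = 80L, tn = 880L, fp = 20L, fn = 20L),
                        class = "confusion_counts"), id = "u1")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_metrics_csv(r, path)
  expect_identical(names(df), c("id", "DSC%", "JSI%", "ACC%", "Precision%",
                                "SE%", "SP%", "FNR", "FPR"))
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$`DSC%`, 80, tolerance = 1e-9)
  expect_equal(back$FPR, 20 / 900, tolerance = 1e-9)
})
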