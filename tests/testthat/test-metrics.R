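test_that("confusion counts match a per-frame per-class loop", {
  set.seed(101)
  for (i in 1:25) {
    b <- random_batch(sample(5:20, 1))
    cc <- confusion_counts(as_targets(b), as_preds(b))
    oc <- oracle_confusion(b$Y, b$P)
    expect_equal(unname(cc$tp), oc$tp)
    expect_equal(unname(cc$fp), oc$fp)
    expect_equal(unname(cc$fn), oc$fn)
    expect_equal(unname(cc$tn), oc$tn)
    expect_equal(unname(cc$tp + cc$fp + cc$fn + cc$tn),
                 rep(nrow(b$Y), 11L))
  }
})

test_that("aggregated metrics match hand-evaluated examples", {
  # pooled totals TP=2, FP=1, FN=1: precision = recall = micro F1 = 2/3
  Y <- matrix(c(1, 1, 0, 1), 4, 1)
  P <- matrix(c(0.9, 0.9, 0.9, 0.1), 4, 1)
  cc <- confusion_counts(Y, P)
  m <- classification_metrics(cc)
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$micro_f1, 2 / 3, tolerance = 1e-12)

  # two classes with F1 = 1.0 (support 3) and 0.0 (support 1)
  Y2 <- cbind(c(1, 1, 1, 0), c(1, 0, 0, 0))
  P2 <- cbind(c(0.9, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.1))
  m2 <- classification_metrics(confusion_counts(Y2, P2))
  expect_equal(m2$macro_f1, 0.75, tolerance = 1e-12)
  expect_equal(m2$per_class$f1, c(1, 0))
  expect_equal(m2$per_class$support, c(3L, 1L))

  # perfect predictions give all ones
  mperf <- classification_metrics(confusion_counts(Y2, Y2 * 0.98 + 0.01))
  for (nm in c("precision", "recall", "micro_f1", "macro_f1", "accuracy")) {
    expect_equal(mperf[[nm]], 1)
  }

  # all-zero counts resolve 0/0 to 0
  mzero <- classification_metrics(confusion_counts(
    matrix(0, 3, 2), matrix(0.1, 3, 2)))
  expect_equal(mzero$precision, 0)
  expect_equal(mzero$recall, 0)
  expect_equal(mzero$micro_f1, 0)
  expect_equal(mzero$macro_f1, 0)
  expect_equal(mzero$accuracy, 1)
})

test_that("regression metrics are masked, pooled and hand-checked", {
  t1 <- list(list(presence = c(1, 1), coords = c(0.5, 0.5, 0.5, 0.5),
                  mask = c(1, 1, 0, 0)))
  p1 <- list(list(probabilities = c(1, 1),
                  coords = c(0.6, 0.8, 0.9, 0.9)))
  r <- regression_metrics(t1, p1)
  expect_equal(r[["mae"]], 0.2, tolerance = 1e-12)
  expect_equal(r[["mse"]], 0.05, tolerance = 1e-12)
  expect_equal(r[["rmse"]], sqrt(0.05), tolerance = 1e-12)

  rp <- regression_metrics(t1, list(list(probabilities = c(1, 1),
                                         coords = c(0.5, 0.5, 0.1, 0.9))))
  expect_equal(unname(rp), c(0, 0, 0))
  expect_error(regression_metrics(
    list(list(presence = 0, coords = c(0, 0), mask = c(0, 0))),
    list(list(probabilities = 0, coords = c(1, 1)))), "masked-in")
})

test_that("regression metrics equal the scalar oracle on random batches", {
  set.seed(33)
  for (i in 1:25) {
    b <- random_batch(sample(5:20, 1))
    if (sum(b$M) == 0) next
    r <- regression_metrics(as_targets(b), as_preds(b))
    o <- oracle_regression(b$Ct, b$Cp, b$M)
    expect_equal(r, o, tolerance = 1e-12)
    expect_equal(r[["rmse"]]^2, r[["mse"]], tolerance = 1e-12)
    expect_lte(r[["mae"]], r[["rmse"]] + 1e-12)
  }
})

test_that("raising the presence threshold never increases recall", {
  set.seed(7)
  b <- random_batch(40)
  last <- Inf
  for (thr in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    m <- classification_metrics(confusion_counts(as_targets(b),
                                                 as_preds(b), thr))
    expect_lte(m$recall, last + 1e-12)
    last <- m$recall
  }
  expect_error(confusion_counts(as_targets(b), as_preds(b), 1.5),
               "threshold")
})

test_that("normalized MAE converts to the printed pixel scale", {
  expect_equal(pixel_error(0.047, 1000), 47)
  expect_equal(pixel_error(0.056, 1000), 56)
  expect_equal(pixel_error(0, 123), 0)
  expect_error(pixel_error(0.1, 0), "positive")
  expect_error(pixel_error(-0.1, 10), ">= 0")
})

test_that("metric reports export the comparison CSV layout", {
  dir <- withr::local_tempdir()
  set.seed(12)
  b <- random_batch(15)
  rep1 <- metrics_report(as_targets(b), as_preds(b))
  path <- file.path(dir, "metrics.csv")
  df <- write_metrics_csv(list(train = rep1, valid = rep1), path)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(back$metric,
               c("precision", "recall", "macro_f1", "micro_f1", "accuracy",
                 "mae", "mse", "rmse"))
  expect_true(all(c("train", "valid") %in% names(back)))
  expect_equal(back$valid[back$metric == "mae"], unname(rep1$mae),
               tolerance = 1e-12)
})
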