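# The printed best-model report row used throughout: per-class precision
# 0.948357/0.984615 and recall 0.914027/0.991035 over supports 442/2454.
gipso_row_cm <- cm_from_counts(tn = 404, fp = 38, fn = 22, tp = 2432)

test_that("confusion counts are conserved and validated", {
  cm <- confusion_matrix(c(0, 1), c(0, 1))
  expect_equal(c(cm$tn, cm$tp, cm$fp, cm$fn), c(1, 1, 0, 0))
  cm2 <- confusion_matrix(c(0, 0), c(1, 1))
  expect_equal(cm2$fp, 2L)
  set.seed(2)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.5); p <- rbinom(50, 1, 0.5)
    cm3 <- confusion_matrix(y, p)
    expect_equal(cm3$tn + cm3$fp + cm3$fn + cm3$tp, 50L)
  }
  expect_error(confusion_matrix(c(0, 1), c(0, 2)), "binary")
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 1)), "length")
})

test_that("the report reproduces the published best-model row to 6 decimals", {
  r <- classification_report(gipso_row_cm)
  expect_equal(r$f1[["normal"]], 0.930876, tolerance = 5e-7)
  expect_equal(r$f1[["anomalous"]], 0.987815, tolerance = 5e-7)
  expect_equal(r$accuracy, 0.979282, tolerance = 5e-7)
  expect_equal(r$precision[["normal"]], 0.948357, tolerance = 5e-7)
  expect_equal(r$macro[["f1"]], 0.959345, tolerance = 5e-7)
  expect_equal(r$weighted[["precision"]], 0.979081, tolerance = 5e-7)
})

test_that("perfect predictions score one everywhere", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 0, 1, 1))
  r <- classification_report(cm)
  expect_equal(unname(c(r$precision, r$recall, r$f1, r$accuracy)), rep(1, 7))
  expect_equal(cohen_kappa(cm), 1)
})

test_that("support-weighted recall equals accuracy on any matrix", {
  for (seed in 1:25) {
    cm <- random_confusion(seed)
    r <- classification_report(cm)
    expect_equal(r$weighted[["recall"]], r$accuracy, tolerance = 1e-12)
  }
})

test_that("kappa identities: chance agreement, label swap, bounded by accuracy", {
  # independent marginals: observed = expected agreement
  expect_equal(cohen_kappa(cm_from_counts(1, 1, 1, 1)), 0)
  expect_equal(cohen_kappa(gipso_row_cm), 0.918695, tolerance = 5e-7)
  for (seed in 26:45) {
    cm <- random_confusion(seed)
    swapped <- cm_from_counts(tn = cm$tp, fp = cm$fn, fn = cm$fp, tp = cm$tn)
    expect_equal(cohen_kappa(cm), cohen_kappa(swapped), tolerance = 1e-12)
    r <- classification_report(cm)
    expect_lte(cohen_kappa(cm), r$accuracy + 1e-12)
  }
  expect_error(cohen_kappa(cm_from_counts(5, 0, 0, 0)), "degenerate")
})

test_that("the error rate complements accuracy", {
  expect_equal(error_rate(confusion_matrix(c(0, 1), c(0, 1))), 0)
  expect_lt(abs(error_rate(gipso_row_cm) - 0.020718), 5e-7)
  expect_equal(error_rate(confusion_matrix(c(0, 1), c(1, 0))), 1)
})

test_that("integer confusion matrices are recovered from printed rows", {
  cm <- reconstruct_confusion(c(0.948357, 0.984615), c(0.914027, 0.991035),
                              c(442, 2454))
  expect_equal(c(cm$tn, cm$fp, cm$fn, cm$tp), c(404L, 38L, 22L, 2432L))

  perfect <- reconstruct_confusion(c(1, 1), c(1, 1), c(10, 20))
  expect_equal(c(perfect$tn, perfect$tp), c(10L, 20L))

  expect_error(reconstruct_confusion(c(1, 1), c(0.5, 1), c(1, 5)),
               "no integer confusion matrix")
})

test_that("threshold sweeps match an exhaustive enumeration and pROC", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  cp <- curve_points(y, s)
  # brute-force sweep over all thresholds between distinct scores
  expect_equal(cp$roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(cp$roc$tpr, c(0, 0.5, 0.5, 1, 1))
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(cp$auc_roc, auc_ref, tolerance = 1e-12)
})

test_that("degenerate score patterns give the expected areas", {
  y <- c(0, 1, 0, 1)
  expect_equal(curve_points(y, c(0, 1, 0.2, 0.9))$auc_roc, 1)
  expect_equal(curve_points(y, rep(0.5, 4))$auc_roc, 0.5)
  expect_error(curve_points(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("report CSV layout mirrors the per-class table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(classification_report(gipso_row_cm), path)
  df <- read.csv(path)
  expect_equal(df$metric, c("precision", "recall", "f1", "support"))
  expect_equal(df$accuracy[1], 0.979282, tolerance = 5e-7)
  expect_equal(df$normal[4], 442)
})
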