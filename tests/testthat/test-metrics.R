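test_that("confusion counts follow the standard definitions", {
  cm <- confusion(c("p", "p", "n", "n"), c("p", "n", "n", "p"), "p")
  expect_equal(unlist(cm[c("TP", "FN", "TN", "FP")]),
               c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  all_pos <- confusion(rep("p", 4), rep("p", 4), "p")
  expect_equal(all_pos$TP, 4L)
  expect_equal(all_pos$FP + all_pos$TN + all_pos$FN, 0L)
  expect_error(confusion(c("p", "n"), "p", "p"), "length")
})

test_that("confusion counts always sum to n", {
  labs <- c("p", "n")
  for (n in 1:6) {
    grid <- expand.grid(rep(list(1:2), 2 * n))
    for (r in seq_len(min(nrow(grid), 64))) {
      truth <- labs[unlist(grid[r, 1:n])]
      pred <- labs[unlist(grid[r, n + 1:n])]
      cm <- confusion(truth, pred, "p")
      expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, n)
    }
  }
})

test_that("the root-node calibration figures of merit are reproduced", {
  cm <- confusion_counts(TP = 165, FN = 0, FP = 5, TN = 264)
  expect_equal(round(accuracy(cm), 4), 0.9885)
  expect_equal(round(tpr(cm), 4), 1.0000)
  expect_equal(round(tnr(cm), 4), 0.9814)
  expect_equal(round(f1(cm), 4), 0.9851)
  expect_equal(round(mcc(cm), 4), 0.9760)
})

test_that("degenerate confusion matrices follow documented conventions", {
  perfect <- confusion_counts(TP = 10, TN = 10, FP = 0, FN = 0)
  for (f in list(accuracy, tpr, tnr, f1, mcc)) expect_equal(f(perfect), 1)
  all_pos <- confusion_counts(TP = 5, FP = 5, TN = 0, FN = 0)
  expect_equal(mcc(all_pos), 0)      # zero denominator factor
  no_neg <- confusion_counts(TP = 5, FN = 1, FP = 0, TN = 0)
  expect_error(tnr(no_neg), "TNR undefined")
  no_pos <- confusion_counts(TP = 0, FN = 0, FP = 2, TN = 3)
  expect_error(tpr(no_pos), "TPR undefined")
  expect_error(confusion_counts(0, 0, 0, 0), "empty")
  expect_error(confusion_counts(-1, 1, 1, 1), "non-negative")
})

test_that("MCC is bounded, symmetric under label swap, and 1 only when perfect", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    truth <- sample(c("p", "n"), n, replace = TRUE)
    pred <- sample(c("p", "n"), n, replace = TRUE)
    cm <- confusion(truth, pred, "p")
    m <- mcc(cm)
    expect_gte(m, -1); expect_lte(m, 1)
    # swapping predicted labels negates MCC (when defined both ways)
    swapped <- confusion(truth, ifelse(pred == "p", "n", "p"), "p")
    if (mcc(cm) != 0 && mcc(swapped) != 0)
      expect_equal(mcc(swapped), -m, tolerance = 1e-12)
    if (m == 1) expect_true(cm$FP == 0L && cm$FN == 0L)
    if (cm$FP == 0L && cm$FN == 0L && cm$TP > 0L && cm$TN > 0L)
      expect_equal(m, 1)
  }
})

test_that("accuracy, TPR, TNR and F1 stay within [0, 1]", {
  set.seed(82)
  for (i in 1:30) {
    cm <- confusion_counts(TP = sample(0:9, 1) + 1, FP = sample(0:9, 1),
                           TN = sample(0:9, 1) + 1, FN = sample(0:9, 1))
    for (f in list(accuracy, tpr, tnr, f1)) {
      v <- f(cm)
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("the 5F-pentyl calibration row is reproduced from its error counts", {
  cm <- confusion_counts(TP = 31, FN = 2, FP = 3, TN = 104)
  expect_equal(round(accuracy(cm), 4), 0.9643)
  expect_equal(round(f1(cm), 4), 0.9254)
  # printed MCC is truncated rather than rounded (exact 0.90208)
  expect_equal(mcc(cm), 0.9020, tolerance = 5e-4)
})
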