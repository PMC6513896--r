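test_that("confusion tallies by (true, predicted) and validates input", {
  cm <- confusion_matrix(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))
  expect_identical(c(cm$TP, cm$TN, cm$FP, cm$FN), c(5L, 5L, 0L, 0L))
  expect_error(confusion_matrix(integer(0), integer(0)), "no results")
  set.seed(23)
  truth <- sample(0:1, 30, replace = TRUE)
  pred <- sample(0:1, 30, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  # hand tally
  expect_identical(cm$TP, sum(truth == 1 & pred == 1))
  expect_identical(cm$FN, sum(truth == 1 & pred == 0))
  expect_identical(cm$FP, sum(truth == 0 & pred == 1))
  expect_identical(cm$TN, sum(truth == 0 & pred == 0))
  expect_identical(cm$TP + cm$FN + cm$FP + cm$TN, 30L)
})

test_that("report reproduces the known mainstream-cohort metrics", {
  rep_a <- diagnostic_report(confusion_counts(TP = 23, FN = 13,
                                              FP = 10, TN = 26))
  expect_equal(rep_a$sensitivity, 23 / 36)
  expect_equal(rep_a$specificity, 26 / 36)
  expect_equal(rep_a$lr_positive, (23 / 36) / (1 - 26 / 36))
  expect_equal(rep_a$lr_negative, (1 - 23 / 36) / (26 / 36))
  expect_equal(rep_a$accuracy, 49 / 72)
  f <- format_report(rep_a)
  expect_identical(unname(f[c("sensitivity", "specificity", "accuracy")]),
                   c("64%", "72%", "68%"))
  expect_identical(unname(f[c("lr_positive", "lr_negative")]),
                   c("2.3", "0.50"))
})

test_that("a perfect classifier yields infinite LR+ and zero LR-", {
  r <- diagnostic_report(confusion_counts(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_identical(r$lr_positive, Inf)
  expect_equal(r$lr_negative, 0)
  expect_identical(unname(r$lr_confidence), c("large", "large"))
  expect_error(diagnostic_report(confusion_counts(3, 2, 0, 0)), "undefined")
})

test_that("report values are invariant to the order of results", {
  set.seed(31)
  truth <- sample(0:1, 40, replace = TRUE, prob = c(.4, .6))
  pred <- sample(0:1, 40, replace = TRUE)
  r1 <- diagnostic_report(confusion_matrix(truth, pred))
  perm <- sample(40)
  r2 <- diagnostic_report(confusion_matrix(truth[perm], pred[perm]))
  expect_equal(r1[c("sensitivity", "specificity", "accuracy", "binomial_p")],
               r2[c("sensitivity", "specificity", "accuracy", "binomial_p")])
})

test_that("exact binomial test behaves at the mode, is symmetric at p0 = .5", {
  expect_equal(binomial_test(36, 72, 0.5), 1.0)
  for (k in c(0, 10, 30, 50)) {
    expect_equal(binomial_test(k, 72, 0.5), binomial_test(72 - k, 72, 0.5))
  }
  expect_error(binomial_test(80, 72, 0.5), "invalid counts")
  expect_error(binomial_test(10, 72, 0), "p0")
  # one-sided option
  expect_equal(binomial_test(49, 72, 0.5, alternative = "greater"),
               sum(dbinom(49:72, 72, 0.5)))
})

test_that("ROC handles perfect separation and total ties", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  r2 <- roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(r2$auc, 0.5)
  expect_identical(nrow(r2$points), 2L)  # (0,0) -> (1,1) diagonal
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoid AUC equals the exhaustive pair-counting oracle", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)  # coarse grid forces ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, ref_auc(scores, labels), tolerance = 1e-12)
    # monotone curve from (0,0) to (1,1)
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("reversing scores maps AUC to its complement", {
  set.seed(41)
  scores <- runif(12)
  labels <- c(0, 1, sample(0:1, 10, replace = TRUE))
  expect_equal(roc_curve(-scores, labels)$auc,
               1 - roc_curve(scores, labels)$auc, tolerance = 1e-12)
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- round(runif(20), 1)
  labels <- c(0, 1, sample(0:1, 18, replace = TRUE))
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
})
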