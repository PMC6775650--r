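test_that("one-vs-all confusion counting matches its definition", {
  truths <- c("a", "a", "b", "b", "c")
  cc <- confusion(truths, truths, "a")
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(2, 0, 0, 3))
  flipped <- c("b", "b", "a", "a", "a")
  cc <- confusion(flipped, truths, "a")
  expect_equal(c(cc$TP, cc$TN), c(0, 0))
  expect_error(confusion(character(0), character(0), "a"), "empty")
  # uncertain-location classifier column: 39 healthy/13 tumor on
  # healthy truth, 0/2 on tumor truth, positive = tumor
  pred <- c(rep("healthy", 39), rep("tumor", 13), rep("tumor", 2))
  truth <- c(rep("healthy", 52), rep("tumor", 2))
  cc <- confusion(pred, truth, "tumor")
  expect_equal(c(cc$TP, cc$FN, cc$FP, cc$TN), c(2, 0, 13, 39))
})

test_that("MCC hits its documented boundary and reference values", {
  expect_equal(mcc(confusion_counts(TP = 5, FP = 0, TN = 7, FN = 0)), 1)
  expect_equal(mcc(confusion_counts(TP = 0, FP = 4, TN = 0, FN = 6)), -1)
  expect_equal(mcc(confusion_counts(TP = 2, FP = 13, TN = 39, FN = 0)),
               78 / sqrt(15 * 2 * 52 * 39), tolerance = 1e-12)
  # zero-denominator convention
  expect_equal(mcc(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 0)), 0)
})

test_that("MCC equals the Pearson correlation of the binary label vectors", {
  for (total in c(2, 5, 8, 12)) {
    for (tab in all_tables_with_total(total)) {
      cc <- confusion_counts(TP = tab["TP"], FP = tab["FP"],
                             TN = tab["TN"], FN = tab["FN"])
      pred <- rep(c(1, 1, 0, 0), tab[c("TP", "FP", "TN", "FN")])
      truth <- rep(c(1, 0, 0, 1), tab[c("TP", "FP", "TN", "FN")])
      r <- suppressWarnings(cor(pred, truth))
      expected <- if (is.na(r)) 0 else r  # zero-variance margin -> 0
      expect_equal(mcc(cc), expected, tolerance = 1e-12)
    }
  }
})

test_that("swapping predicted positives and negatives negates MCC", {
  set.seed(4)
  for (i in 1:25) {
    tab <- as.integer(rmultinom(1, 40, rep(0.25, 4)))
    cc <- confusion_counts(TP = tab[1], FP = tab[2], TN = tab[3], FN = tab[4])
    sw <- confusion_counts(TP = tab[4], FP = tab[3], TN = tab[2], FN = tab[1])
    expect_equal(mcc(sw), -mcc(cc), tolerance = 1e-12)
  }
})

test_that("accuracy, sensitivity and specificity follow their definitions", {
  cc <- confusion_counts(TP = 2, FP = 13, TN = 39, FN = 0)
  r <- basic_rates(cc)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 39 / 52)
  expect_equal(basic_rates(confusion_counts(1, 1, 1, 1))$accuracy, 0.5)
  # undefined denominators are NA, not 0
  expect_true(is.na(basic_rates(confusion_counts(TP = 0, FP = 2, TN = 3,
                                                 FN = 0))$sensitivity))
  expect_true(is.na(basic_rates(confusion_counts(TP = 2, FP = 0, TN = 0,
                                                 FN = 1))$specificity))
})

test_that("weighted accuracy is the count-weighted mean", {
  acc <- c(fat = 0.92, wall = 0.89, tumor = 0.94)
  n <- c(fat = 402, wall = 282, tumor = 87)
  expect_equal(weighted_accuracy(acc, n),
               (0.92 * 402 + 0.89 * 282 + 0.94 * 87) / 771)
  expect_equal(weighted_accuracy(c(a = 0.5, b = 0.9), c(a = 10, b = 10)),
               0.7)
  expect_equal(weighted_accuracy(c(a = 0.81), c(a = 7)), 0.81)
  expect_error(weighted_accuracy(c(a = 1), c(b = 1)), "names")
})

test_that("ROC sweeps reproduce known curves and AUC values", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_equal(tail(r$points$tpr, 1), 1)
  expect_equal(roc_curve(rep(0.3, 8), c(1, 0, 1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- round(rnorm(n), 1)  # coarse: force ties
    u <- wilcox.test(scores[truth], scores[!truth],
                     exact = FALSE)$statistic
    expect_equal(roc_curve(scores, truth)$auc,
                 as.numeric(u) / (sum(truth) * sum(!truth)),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(60)
  truth <- rbinom(60, 1, plogis(scores))
  if (any(truth == 1) && any(truth == 0)) {
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
    expect_equal(roc_curve(scores, truth)$auc, ref, tolerance = 1e-10)
  }
})

test_that("the metrics report aggregates repeats with mean and SD", {
  g <- gaussian_classes(n_per_class = 20, sep = 7, seed = 15)
  pr <- cross_validate(g$x, g$measurements, g$labels, k = 4, repeats = 3,
                       seed = 2)
  rep_ <- metrics_report(pr)
  expect_setequal(rep_$per_class$class, c("fat", "wall", "tumor"))
  expect_true(all(rep_$per_class$mcc_mean >= -1 &
                    rep_$per_class$mcc_mean <= 1))
  expect_true(all(rep_$per_class$accuracy_mean >= 0 &
                    rep_$per_class$accuracy_mean <= 1))
  expect_equal(rep_$weighted_accuracy,
               weighted_accuracy(
                 setNames(rep_$per_class$accuracy_mean, rep_$per_class$class),
                 setNames(rep_$per_class$n, rep_$per_class$class)))
  expect_setequal(names(rep_$roc), c("fat", "wall", "tumor"))
  for (r in rep_$roc) expect_true(r$auc >= 0 && r$auc <= 1)
  # location level exists and has one record per location x repeat
  rep_loc <- metrics_report(pr, level = "location")
  expect_identical(rep_loc$level, "location")
})
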