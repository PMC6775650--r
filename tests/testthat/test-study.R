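test_that("the depth rule labels tumor, non-tumor and inconclusive locations", {
  loc <- data.frame(
    true_class = c("tumor", "tumor", "tumor", "wall", "fat"),
    tumor_depth_mm = c(0, 2.0, 1.0, NA, NA),
    tumor_extent_mm = c(2, 3, 0.3, NA, NA))
  expect_equal(depth_label(loc),
               c("tumor", "non_tumor", "excluded", "non_tumor", "non_tumor"))
  # partition property under arbitrary valid rules
  set.seed(6)
  tum <- data.frame(true_class = "tumor",
                    tumor_depth_mm = runif(50, 0, 5),
                    tumor_extent_mm = runif(50, 0.05, 10))
  for (rule in list(depth_rule(1, 0.5), depth_rule(3, 1),
                    depth_rule(0.2, 0.1))) {
    lab <- depth_label(tum, rule)
    expect_true(all(lab %in% c("tumor", "non_tumor", "excluded")))
    within <- tum$tumor_depth_mm <= rule$max_depth_mm
    expect_equal(lab == "tumor",
                 within & tum$tumor_extent_mm >= rule$min_extent_mm)
    expect_equal(lab == "excluded",
                 within & tum$tumor_extent_mm < rule$min_extent_mm)
  }
  bad <- data.frame(true_class = "tumor", tumor_depth_mm = NA_real_,
                    tumor_extent_mm = 1)
  expect_error(depth_label(bad), "depth")
})

test_that("zero-FN calibration matches brute-force enumeration", {
  # documented example: threshold just below the lowest tumor score
  cal <- zero_fn_threshold(c(0.9, 0.8, 0.7, 0.95), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cal$fn, 0)
  expect_equal(cal$fp, 1)
  expect_lt(cal$threshold, 0.8)
  expect_gt(cal$threshold, 0.7)

  # separable case: no false positives
  expect_equal(zero_fn_threshold(c(2, 3, 0.5, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE))$fp, 0)

  # a healthy tie with the minimum tumor score is a false positive
  expect_equal(zero_fn_threshold(c(1, 1, 0.2), c(TRUE, FALSE, FALSE))$fp, 1)

  # random instances: FN always 0, FP minimal over all possible thresholds
  set.seed(9)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), 2)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth)) truth[sample(n, 1)] <- TRUE
    cal <- zero_fn_threshold(scores, truth)
    called <- scores > cal$threshold
    expect_equal(sum(truth & !called), 0)
    candidates <- c(sort(unique(scores)) - 1e-9, max(scores) + 1)
    feasible_fp <- sapply(candidates, function(t) {
      if (any(truth & scores <= t)) NA else sum(!truth & scores > t)
    })
    expect_equal(cal$fp, min(feasible_fp, na.rm = TRUE))
  }
  expect_error(zero_fn_threshold(1:3, c(FALSE, FALSE, FALSE)), "no tumor")
})

test_that("lowering the threshold trades specificity for sensitivity monotonically", {
  set.seed(14)
  scores <- rnorm(80)
  truth <- rbinom(80, 1, plogis(2 * scores)) == 1
  thresholds <- sort(rnorm(15))
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    called <- scores > thresholds[i]
    sens[i] <- sum(called & truth) / sum(truth)
    spec[i] <- sum(!called & !truth) / sum(!truth)
  }
  # thresholds ascending: sensitivity never rises, specificity never falls
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("the depth sweep relabels, retrains and stays deterministic", {
  ds <- simulate_dataset(tiny_config(seed = 33, n_patients = 10))
  fx <- preprocess_dataset(ds)
  sw <- depth_sweep(ds, depths = c(1.5, Inf), k = 5, repeats = 2, seed = 4,
                    features = fx)
  expect_equal(sw$max_depth_mm, c(1.5, Inf))
  expect_true(all(!sw$empty))
  expect_true(all(sw$mcc_mean >= -1 & sw$mcc_mean <= 1))
  sw2 <- depth_sweep(ds, depths = c(1.5, Inf), k = 5, repeats = 2, seed = 4,
                     features = fx)
  expect_identical(sw, sw2)
  # more depth-1.5 tumors than surface-only tumors are labeled tumor
  expect_gte(sw$n_tumor_locations[2], sw$n_tumor_locations[1])
})

test_that("a dataset with all tumors at the surface is depth-invariant", {
  ds <- simulate_dataset(tiny_config(seed = 35, n_patients = 8,
                                     depth_p_surface = 1,
                                     inconclusive_fraction = 0))
  for (d in c(0, 1.5, 4)) {
    rl <- drscascade:::rule_labels(ds$locations, depth_rule(d))
    expect_true(all(rl$keep))
    expect_equal(rl$labels[ds$locations$true_class == "tumor"],
                 rep("tumor", sum(ds$locations$true_class == "tumor")))
  }
})

test_that("an empty tumor bin is flagged, not silently dropped", {
  ds <- simulate_dataset(tiny_config(seed = 36, n_patients = 8,
                                     depth_p_surface = 0,
                                     depth_mean_mm = 4, depth_max_mm = 6))
  # with every tumor buried deeper than 0.05 mm, the 0.05 mm bin is empty
  if (all(ds$locations$tumor_depth_mm > 0.05, na.rm = TRUE)) {
    fx <- preprocess_dataset(ds)
    sw <- depth_sweep(ds, depths = c(0.05), k = 4, repeats = 1, seed = 2,
                      features = fx)
    expect_true(sw$empty[1])
    expect_true(is.na(sw$mcc_mean[1]))
    expect_equal(sw$n_tumor_locations[1], 0L)
  }
})

test_that("surgeon comparison calibrates on certain and evaluates uncertain locations", {
  ds <- simulate_dataset(tiny_config(seed = 41, n_patients = 12,
                                     surgeon_uncertain_fraction = 0.35))
  cmp <- compare_with_surgeon(ds, k = 5, repeats = 2, seed = 6)
  expect_s3_class(cmp$classifier, "drs_confusion")
  expect_s3_class(cmp$surgeon, "drs_confusion")
  expect_equal(cmp$calibration$fn, 0)
  expect_equal(cmp$n_uncertain + cmp$n_certain,
               sum(drscascade:::rule_labels(ds$locations)$keep))
  # classifier sensitivity on uncertain subset should not be NA when tumors
  # are present there
  if (cmp$classifier$TP + cmp$classifier$FN > 0) {
    expect_true(cmp$classifier_sensitivity >= 0)
  }
})

test_that("identical calls to histopathology give zero FP and FN", {
  pred <- c("tumor", "tumor", "healthy", "healthy")
  cc <- confusion(pred, pred, "tumor")
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0)
  expect_equal(basic_rates(cc)$accuracy, 1)
})
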