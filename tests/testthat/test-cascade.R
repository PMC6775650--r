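test_that("well-separated classes are fit perfectly and deterministically", {
  g <- gaussian_classes(n_per_class = 25, sep = 8, seed = 2)
  m1 <- train_cascade(g$x, g$labels)
  m2 <- train_cascade(g$x, g$labels)
  p <- predict(m1, g$x)
  expect_equal(p$predicted_class, g$labels)
  # convex fit on fixed data: identical weights across runs
  expect_identical(m1$w_fat, m2$w_fat)
  expect_identical(m1$w_tumor, m2$w_tumor)
})

test_that("training rejects degenerate label sets", {
  g <- gaussian_classes(n_per_class = 10, seed = 3)
  only_fat_wall <- g$labels %in% c("fat", "wall")
  expect_error(train_cascade(g$x[only_fat_wall, ], g$labels[only_fat_wall]),
               "wall and tumor")
  expect_error(train_cascade(g$x, rep("fat", nrow(g$x))), "wall and tumor")
  expect_error(train_cascade(g$x, sample(c("a", "b"), nrow(g$x), TRUE)),
               "fat, wall or tumor")
})

test_that("cascade routing follows the two-stage workflow", {
  g <- gaussian_classes(n_per_class = 30, sep = 8, seed = 4)
  m <- train_cascade(g$x, g$labels)
  fat_centroid <- colMeans(g$x[g$labels == "fat", ])
  p <- predict(m, fat_centroid)
  expect_identical(p$predicted_class, "fat")
  expect_true(is.na(p$score_tumor))  # stage two not consulted
  expect_false(is.na(predict(m, fat_centroid,
                             keep_tumor_scores = TRUE)$score_tumor))

  # a non-fat spectrum scoring exactly at the threshold is called wall
  wall_pt <- colMeans(g$x[g$labels == "wall", ])
  s <- drscascade:::cascade_scores(m, matrix(wall_pt, 1))
  m_tie <- m
  m_tie$tumor_threshold <- s$score_tumor
  expect_identical(predict(m_tie, wall_pt)$predicted_class, "wall")

  expect_error(predict(m, matrix(0, 1, 3)), "dimensionality")
})

test_that("raising the tumor threshold never creates new tumor calls", {
  g <- gaussian_classes(n_per_class = 40, sep = 2.5, seed = 5)
  m <- train_cascade(g$x, g$labels)
  thresholds <- c(-2, -0.5, 0, 0.5, 2)
  calls <- sapply(thresholds, function(t) {
    m$tumor_threshold <- t
    predict(m, g$x)$predicted_class == "tumor"
  })
  for (j in seq_len(ncol(calls) - 1)) {
    expect_true(all(calls[, j] | !calls[, j + 1]))  # tumor set shrinks
  }
})

test_that("permuted labels give near-zero cross-validated MCC", {
  set.seed(11)
  g <- gaussian_classes(n_per_class = 200, d = 6, sep = 5, seed = 11)
  shuffled <- sample(g$labels)
  pr <- cross_validate(g$x, g$measurements, shuffled, k = 5, repeats = 1,
                       seed = 2)
  for (cls in c("fat", "wall", "tumor")) {
    m <- mcc(confusion(pr$predicted_class, pr$true_class, cls))
    expect_lt(abs(m), 0.15)
  }
})

test_that("cross-validation partitions locations and is seed-deterministic", {
  g <- gaussian_classes(n_per_class = 20, seed = 6)
  pr <- cross_validate(g$x, g$measurements, g$labels, k = 5, repeats = 3,
                       seed = 7)
  # every measurement gets exactly one out-of-fold prediction per repeat
  expect_true(all(table(pr$measurement_id, pr$repeat_index) == 1))
  expect_equal(nrow(pr), 3 * nrow(g$x))
  # disjoint folds covering the whole dataset within each repeat
  for (r in 1:3) {
    d <- pr[pr$repeat_index == r, ]
    expect_setequal(d$measurement_id, g$measurements$measurement_id)
  }
  pr2 <- cross_validate(g$x, g$measurements, g$labels, k = 5, repeats = 3,
                        seed = 7)
  expect_identical(pr, pr2)
  expect_error(cross_validate(g$x, g$measurements, g$labels, k = 25),
               "fewer than")
})

test_that("leave-one-location-out uses as many folds as locations", {
  g <- gaussian_classes(n_per_class = 12, sep = 7, seed = 8)
  pr <- cross_validate(g$x, g$measurements, g$labels, k = 12, repeats = 1,
                       seed = 1)
  expect_equal(sort(unique(pr$fold)), 1:12)
  expect_equal(nrow(pr), nrow(g$x))
})

test_that("replicates stay together and grouping keeps patients in one fold", {
  ds <- simulate_dataset(tiny_config(seed = 19, n_patients = 8))
  fx <- preprocess_dataset(ds)
  lab <- ds$locations$true_class[match(ds$measurements$location_id,
                                       ds$locations$location_id)]
  pr <- cross_validate(fx$features, ds$measurements, lab, k = 4,
                       repeats = 2, seed = 3)
  # all replicates of a location share the fold
  expect_true(all(tapply(pr$fold, interaction(pr$location_id,
                                              pr$repeat_index),
                         function(f) length(unique(f))) == 1))
  prg <- cross_validate(fx$features, ds$measurements, lab, k = 4,
                        repeats = 2, seed = 3, group_by_patient = TRUE)
  folds_per_patient <- tapply(
    prg$fold, interaction(prg$patient_id, prg$repeat_index),
    function(f) length(unique(f)))
  expect_true(all(folds_per_patient == 1))
})

test_that("location aggregation votes replicates and averages scores", {
  pr <- data.frame(
    measurement_id = sprintf("M%d", 1:6),
    location_id = rep(c("L1", "L2"), each = 3),
    patient_id = "P1", repeat_index = 1L, fold = 1L,
    true_class = rep(c("tumor", "wall"), each = 3),
    score_fat = c(-1, -1, -1, -2, -2, -2),
    score_tumor = c(1, 2, -0.5, -1, -1, 4),
    predicted_class = c("tumor", "tumor", "wall", "wall", "wall", "tumor"),
    stringsAsFactors = FALSE)
  agg <- aggregate_locations(pr)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$predicted_class[agg$location_id == "L1"], "tumor")
  expect_equal(agg$predicted_class[agg$location_id == "L2"], "wall")
  expect_equal(agg$score_tumor[agg$location_id == "L1"], mean(c(1, 2, -0.5)))
})

test_that("cascade models survive a JSON round trip", {
  g <- gaussian_classes(n_per_class = 15, seed = 9)
  m <- train_cascade(g$x, g$labels, tumor_threshold = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_cascade(m, path)
  m2 <- read_cascade(path)
  expect_equal(m2$w_fat, m$w_fat)
  expect_equal(m2$w_tumor, m$w_tumor)
  expect_equal(m2$tumor_threshold, 0.25)
  expect_equal(predict(m2, g$x), predict(m, g$x))
})
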