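make_aug <- function(n = 200L, seed = 51L, w = 8L) {
  set.seed(seed)
  s <- sensorSeries(matrix(rnorm(n * 3), ncol = 3),
                    labels = rep(c("a", "b"), length.out = n))
  sh <- generateShadowBatch(s, fixedCalibration(s, w), static_config())
  list(series = s, shadow = sh)
}

test_that("augmentation doubles predictors and orders shadows after originals", {
  x <- make_aug()
  aug <- augmentDataset(x$series, x$shadow, policy = "drop")
  expect_identical(ncol(predictors(aug)), 6L)
  expect_identical(colnames(predictors(aug))[4:6],
                   paste0(featureNames(x$series), "_shadow"))
  # drop removes exactly the w - 1 warm-up rows
  expect_identical(nrow(predictors(aug)), 200L - 7L)
  expect_identical(droppedRows(aug), 1:7)
  # mark keeps all rows with NA warm-ups
  m <- augmentDataset(x$series, x$shadow, policy = "mark")
  expect_identical(nrow(predictors(m)), 200L)
  expect_true(all(is.na(predictors(m)[1:7, 4:6])))
  # backfill copies the first known shadow backwards
  b <- augmentDataset(x$series, x$shadow, policy = "backfill")
  expect_false(anyNA(predictors(b)))
  expect_equal(predictors(b)[1, 4], predictors(b)[8, 4])
  expect_error(
    augmentDataset(x$series,
                   generateShadowBatch(
                     sensorSeries(matrix(rnorm(20), ncol = 2)),
                     fixedCalibration(sensorSeries(matrix(rnorm(20),
                                                          ncol = 2)), 4L),
                     static_config()),
                   "drop"),
    "shapes differ")
})

test_that("Haar transform matches the hand oracle and replaces features", {
  # alternating +1/-1, w = 2: approximation 0, detail magnitude 1
  s <- sensorSeries(cbind(alt = rep(c(1, -1), 30)))
  hf <- haarFeatures(s, 2L)
  v <- shadowValues(hf)
  known <- !is.na(v[, 1])
  expect_equal(unname(v[known, 1]), rep(0, sum(known)))
  expect_equal(unname(abs(v[known, 2])), rep(1, sum(known)))
  # constant series: all detail coefficients 0
  sc <- sensorSeries(cbind(c = rep(3, 40)))
  vd <- shadowValues(haarFeatures(sc, 4L))
  expect_equal(unname(vd[!is.na(vd[, 2]), 2]), rep(0, 37))
  # M features map to 2M coefficients
  s3 <- sensorSeries(matrix(rnorm(120), ncol = 3))
  expect_identical(ncol(shadowValues(haarFeatures(s3, 4L))), 6L)
  expect_error(haarFeatures(s3, 3L), "power of two")
})

test_that("kappa matches hand oracles and its range", {
  expect_equal(cohenKappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  expect_equal(cohenKappa(diag(c(7, 9, 4))), 1)
  # rank-one: marginals independent -> 0
  expect_equal(cohenKappa(outer(c(2, 3), c(4, 6))), 0)
  expect_error(cohenKappa(matrix(0, 2, 2)), "empty")
})

test_that("macro-F matches hand oracles and exclusion rule", {
  cm <- matrix(c(40, 20, 10, 30), 2)      # truth rows, prediction cols
  # class 1: P = 40/60, R = 40/50 -> F = 16/22
  f1 <- 16 / 22
  f2 <- 2 * (30 / 40) * (30 / 50) / (30 / 40 + 30 / 50)
  expect_equal(macroF(cm), mean(c(f1, f2)))
  expect_equal(macroF(diag(c(5, 5, 5))), 1)
  # class absent from both truth and prediction is excluded
  cm3 <- matrix(0L, 3, 3); cm3[1, 1] <- 5L; cm3[2, 2] <- 5L
  expect_equal(macroF(cm3), 1)
})

test_that("a perfectly separable table is learned exactly by the tree", {
  set.seed(52)
  X <- rbind(matrix(rnorm(150, 0), ncol = 3),
             matrix(rnorm(150, 10), ncol = 3))
  d <- list(predictors = X, labels = rep(c("a", "b"), each = 50))
  rep <- trainEval(d, "decision_tree", "full_training")
  expect_equal(rep@accuracy, 1)
  expect_equal(rep@kappa, 1)
  expect_equal(rep@macroF, 1)
  expect_identical(sum(confusionMatrix(rep)), 100L)
})

test_that("every learner kind runs and reports coherent metrics", {
  set.seed(53)
  n <- 400   # enough rows for the Hoeffding tree to pass its grace period
  X <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 4), ncol = 2))
  y <- rep(c("a", "b"), each = n)
  ord <- sample(2 * n)   # interleave classes as a stream would
  tr <- list(predictors = X[ord, ], labels = y[ord])
  te <- list(predictors = tr$predictors + rnorm(length(X), sd = 0.1),
             labels = tr$labels)
  for (lr in c("decision_tree", "svm", "ann",
               "naive_bayes", "knn1", "hoeffding_tree")) {
    for (mode in c("full_training", "train_then_test")) {
      rep <- trainEval(tr, lr, mode, test = te, seed = 7L)
      expect_true(rep@accuracy >= 0 && rep@accuracy <= 1)
      expect_true(rep@kappa >= -1 && rep@kappa <= 1)
      expect_true(rep@macroF >= 0 && rep@macroF <= 1)
      cm <- confusionMatrix(rep)
      expect_equal(rep@accuracy, sum(diag(cm)) / sum(cm))
      # both classes are easy: any sensible learner beats chance
      expect_gt(rep@accuracy, 0.7)
    }
  }
  expect_error(trainEval(tr, "boosted_stump", "full_training"), "unknown")
  expect_error(trainEval(tr, "svm", "train_then_test"), "test dataset")
})

test_that("comparison table covers strategies x learners x modes", {
  spec <- defaultActivitySpec(segmentLength = 100L)
  tab <- compareStrategies(spec,
                           learners = c("decision_tree", "naive_bayes"),
                           seeds = 1L)
  expect_identical(nrow(tab), 3L * 2L * 2L)
  expect_true(all(tab$kappa_band %in% c("high", "general", "low")))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  # determinism across runs (training time is wall clock, so excluded)
  tab2 <- compareStrategies(spec,
                            learners = c("decision_tree", "naive_bayes"),
                            seeds = 1L)
  keep <- setdiff(names(tab), "train_time")
  expect_identical(tab[keep], tab2[keep])
})

test_that("shadow augmentation beats originals out of sample for the tree", {
  # scaled-down directional check; the acceptance test runs the full
  # 20-seed protocol at the default stream size
  res <- vapply(1:4, function(seed) {
    spec <- defaultActivitySpec(segmentLength = 400L, seed = seed)
    tr <- simulateActivityStream(spec)
    te <- simulateActivityStream(defaultActivitySpec(segmentLength = 400L,
                                                     seed = seed + 500000L))
    cal <- calibrate(tr)
    cfg <- shadowConfig()
    augTr <- augmentDataset(tr, generateShadowBatch(tr, cal, cfg), "drop")
    augTe <- augmentDataset(te, generateShadowBatch(te, cal, cfg), "drop")
    orTr <- list(predictors = sensorValues(tr), labels = activityLabels(tr))
    orTe <- list(predictors = sensorValues(te), labels = activityLabels(te))
    c(trainEval(orTr, "decision_tree", "train_then_test", orTe)@accuracy,
      trainEval(augTr, "decision_tree", "train_then_test", augTe)@accuracy)
  }, numeric(2))
  expect_gt(mean(res[2, ]), mean(res[1, ]))
})
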