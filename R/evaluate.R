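# Dataset augmentation, the Haar baseline, the classifier harness (batch
# and incremental) and the agreement metrics used in the three-way
# comparison: original features vs Haar-transformed vs shadow-augmented.

#' Augment a series with its shadow features
#'
#' Binds the M shadow columns to the right of the M original columns, so
#' column j + M is always the shadow of column j. Warm-up slots are handled
#' by the policy: `"mark"` keeps them as NA (serialized "?"), `"drop"`
#' removes every row with an unknown slot, `"backfill"` copies the first
#' known shadow value backwards.
#'
#' @param series a [SensorSeries-class].
#' @param shadow the matching [ShadowSeries-class].
#' @param policy "mark", "drop" or "backfill".
#' @return an [AugmentedDataset-class] with 2M predictors.
#' @examples
#' s <- sensorSeries(matrix(rnorm(600), ncol = 3))
#' sh <- generateShadowBatch(s, fixedCalibration(s, 8L),
#'                           shadowConfig(dynamicWindow = FALSE))
#' ncol(predictors(augmentDataset(s, sh, "drop")))  # 6
#' @export
augmentDataset <- function(series, shadow,
                           policy = c("mark", "drop", "backfill")) {
  policy <- match.arg(policy)
  if (!identical(dim(series@values), dim(shadow@values)))
    stop("series and shadow shapes differ")
  sv <- shadowValues(shadow)           # NA on warm-up slots
  labs <- series@labels
  dropped <- integer()
  if (policy == "drop") {
    bad <- which(rowSums(is.na(sv)) > 0)
    dropped <- bad
    keep <- setdiff(seq_len(nrow(sv)), bad)
    pred <- cbind(series@values[keep, , drop = FALSE],
                  sv[keep, , drop = FALSE])
    if (length(labs)) labs <- labs[keep]
  } else {
    if (policy == "backfill") {
      for (j in seq_len(ncol(sv))) {
        known <- which(!is.na(sv[, j]))
        if (length(known) && known[1L] > 1L)
          sv[seq_len(known[1L] - 1L), j] <- sv[known[1L], j]
      }
    }
    pred <- cbind(series@values, sv)
  }
  colnames(pred) <- c(featureNames(series),
                      paste0(featureNames(series), SHADOW_SUFFIX))
  new("AugmentedDataset", predictors = pred, labels = labs,
      policy = policy, droppedRows = as.integer(dropped))
}

#' Trailing-window Haar features (baseline transformation)
#'
#' The comparison baseline: a level-1 Haar transform over a trailing window
#' of length w per feature. Consecutive samples are paired; the
#' approximation coefficient is the mean of the pair averages, the detail
#' coefficient the mean of the pair half-differences (newest minus older
#' within each pair, divided by 2). Unlike shadow features this is a
#' transformation: the 2M coefficients REPLACE the M originals. The first
#' w - 1 slots are unknown.
#'
#' @param series a [SensorSeries-class].
#' @param w window length, a power of two >= 2.
#' @return a [ShadowSeries-class] holding the 2M coefficient columns
#'   (`<feature>_haarA`, `<feature>_haarD`) with the warm-up mask.
#' @examples
#' s <- sensorSeries(matrix(rep(c(1, -1), 50), ncol = 1))
#' colMeans(shadowValues(haarFeatures(s, 2L)), na.rm = TRUE)
#' @export
haarFeatures <- function(series, w = 8L) {
  w <- as.integer(w)
  if (w < 2L || bitwAnd(w, w - 1L) != 0L)
    stop("w must be a power of two >= 2")
  n <- nSamples(series)
  m <- nFeatures(series)
  vals <- matrix(NA_real_, n, 2L * m)
  mask <- matrix(TRUE, n, 2L * m)
  half <- w %/% 2L
  for (j in seq_len(m)) {
    x <- series@values[, j]
    if (n >= w) {
      for (i in w:n) {
        win <- x[(i - w + 1L):i]
        newer <- win[seq(2L, w, by = 2L)]
        older <- win[seq(1L, w, by = 2L)]
        vals[i, j] <- mean((newer + older) / 2)
        vals[i, j + m] <- mean((newer - older) / 2)
        mask[i, c(j, j + m)] <- FALSE
      }
    }
  }
  vals[mask] <- 0
  colnames(vals) <- c(paste0(featureNames(series), "_haarA"),
                      paste0(featureNames(series), "_haarD"))
  colnames(mask) <- colnames(vals)
  new("ShadowSeries", values = vals, unknownMask = mask)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)} with the
#' marginal-product expected agreement; 0 when the marginals force
#' \eqn{p_e = 1}.
#'
#' @param confusion square integer matrix, rows = truth, cols = prediction.
#' @return numeric in [-1, 1].
#' @examples
#' cohenKappa(matrix(c(40, 20, 10, 30), 2))  # 0.4
#' @export
cohenKappa <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Macro-averaged F-measure from a confusion matrix
#'
#' Unweighted mean over classes of 2PR/(P + R). A class with P + R = 0
#' contributes 0; a class absent from both truth and prediction (empty row
#' and column) is excluded from the mean rather than counted as a failure.
#'
#' @inheritParams cohenKappa
#' @return numeric in [0, 1].
#' @examples
#' macroF(matrix(c(40, 20, 10, 30), 2))
#' @export
macroF <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  keep <- rs + cs > 0
  f <- vapply(which(keep), function(k) {
    tp <- confusion[k, k]
    p <- if (cs[k] > 0) tp / cs[k] else 0
    r <- if (rs[k] > 0) tp / rs[k] else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f)
}

.confusion_from <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

.report_from <- function(truth, pred, trainTime) {
  cm <- unclass(.confusion_from(truth, pred))
  storage.mode(cm) <- "integer"
  new("EvalReport",
      accuracy = sum(diag(cm)) / sum(cm),
      kappa = cohenKappa(cm),
      macroF = macroF(cm),
      trainTime = trainTime,
      confusion = cm)
}

BATCH_LEARNERS <- c("decision_tree", "svm", "ann")
INCREMENTAL_LEARNERS <- c("naive_bayes", "knn1", "hoeffding_tree")

.fit_batch <- function(kind, X, y, seed) {
  df <- data.frame(X, check.names = FALSE)
  names(df) <- paste0("f", seq_len(ncol(X)))   # syntactic names for formulas
  df$.class <- factor(y)
  switch(kind,
    decision_tree = {
      fit <- rpart::rpart(.class ~ ., df, method = "class")
      function(Xt) {
        dft <- data.frame(Xt, check.names = FALSE)
        names(dft) <- paste0("f", seq_len(ncol(Xt)))
        as.character(predict(fit, dft, type = "class"))
      }
    },
    svm = {
      fit <- e1071::svm(.class ~ ., df)
      function(Xt) {
        dft <- data.frame(Xt, check.names = FALSE)
        names(dft) <- paste0("f", seq_len(ncol(Xt)))
        as.character(predict(fit, dft))
      }
    },
    ann = {
      p <- ncol(X)
      size <- 2L * p
      k <- nlevels(df$.class)
      fit <- with_seed(seed, nnet::nnet(
        .class ~ ., df, size = size, decay = 5e-4, maxit = 150,
        MaxNWts = (p + 1L) * size + (size + 1L) * k + 1L, trace = FALSE))
      function(Xt) {
        dft <- data.frame(Xt, check.names = FALSE)
        names(dft) <- paste0("f", seq_len(ncol(Xt)))
        as.character(predict(fit, dft, type = "class"))
      }
    },
    stop("unknown batch learner: ", kind)
  )
}

#' Train and evaluate one learner on one dataset
#'
#' Batch learners (`decision_tree` = rpart, `svm` = e1071, `ann` = nnet
#' with one hidden layer of width 2 x predictors) fit on the whole training
#' table. Incremental learners (`naive_bayes`, `knn1`, `hoeffding_tree`)
#' consume rows one at a time. Modes: `"full_training"` evaluates on the
#' training source itself (incremental learners prequentially,
#' test-then-train); `"train_then_test"` evaluates on a held-out dataset —
#' for shadow features the test stream's shadows must have been generated
#' from the test stream's own history with training-time calibration
#' constants, which is how [compareStrategies()] builds them.
#'
#' @param train an [AugmentedDataset-class] (or list with `predictors`,
#'   `labels`) used for training.
#' @param learner one of the six learner kinds.
#' @param mode "full_training" or "train_then_test".
#' @param test dataset for train_then_test mode.
#' @param seed integer; fixes the neural-net initialisation.
#' @return an [EvalReport-class].
#' @export
trainEval <- function(train, learner,
                      mode = c("full_training", "train_then_test"),
                      test = NULL, seed = 1L) {
  mode <- match.arg(mode)
  Xtr <- if (is(train, "AugmentedDataset")) train@predictors
         else train$predictors
  ytr <- if (is(train, "AugmentedDataset")) train@labels else train$labels
  if (!length(ytr)) stop("training data must be labeled")
  if (mode == "train_then_test") {
    if (is.null(test)) stop("train_then_test mode needs a test dataset")
    Xte <- if (is(test, "AugmentedDataset")) test@predictors
           else test$predictors
    yte <- if (is(test, "AugmentedDataset")) test@labels else test$labels
  } else {
    Xte <- Xtr
    yte <- ytr
  }
  if (learner %in% BATCH_LEARNERS) {
    t0 <- proc.time()[["elapsed"]]
    predictor <- .fit_batch(learner, Xtr, ytr, seed)
    tt <- proc.time()[["elapsed"]] - t0
    pred <- predictor(Xte)
    return(.report_from(yte, pred, tt))
  }
  if (!learner %in% INCREMENTAL_LEARNERS)
    stop("unknown learner: ", learner)
  mdl <- .incremental_learner(learner, ncol(Xtr))
  majority <- function(seen) if (length(seen)) names(which.max(table(seen)))
                             else NA_character_
  if (mode == "full_training") {
    # prequential: predict each row before training on it
    pred <- character(nrow(Xtr))
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(nrow(Xtr))) {
      p <- mdl$predict(Xtr[i, ])
      if (is.na(p)) p <- majority(ytr[seq_len(i - 1L)])
      if (is.na(p)) p <- ytr[i]
      pred[i] <- p
      mdl$train(Xtr[i, ], ytr[i])
    }
    tt <- proc.time()[["elapsed"]] - t0
    return(.report_from(ytr, pred, tt))
  }
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(Xtr))) mdl$train(Xtr[i, ], ytr[i])
  tt <- proc.time()[["elapsed"]] - t0
  maj <- majority(ytr)
  pred <- vapply(seq_len(nrow(Xte)), function(i) {
    p <- mdl$predict(Xte[i, ])
    if (is.na(p)) maj else p
  }, character(1))
  .report_from(yte, pred, tt)
}

.kappa_band <- function(kappa) {
  if (kappa >= 0.75) "high" else if (kappa >= 0.4) "general" else "low"
}

.strategy_datasets <- function(series, strategy, config, calibration,
                               haarWindow) {
  switch(strategy,
    original = {
      labs <- series@labels
      list(predictors = series@values, labels = labs)
    },
    haar = {
      hf <- haarFeatures(series, haarWindow)
      sv <- shadowValues(hf)
      keep <- which(rowSums(is.na(sv)) == 0)
      list(predictors = sv[keep, , drop = FALSE],
           labels = series@labels[keep])
    },
    shadow = {
      sh <- generateShadowBatch(series, calibration, config)
      augmentDataset(series, sh, policy = "drop")
    },
    stop("unknown strategy: ", strategy)
  )
}

#' Compare original, Haar and shadow strategies across learners
#'
#' Reproduces the comparison protocol on synthetic streams: for each seed a
#' training stream and an independently seeded test stream ("another
#' volunteer") are generated from the same activity spec; each
#' pre-processing strategy x learner x testing mode is evaluated and the
#' reports are seed-averaged. Shadow features are generated per-stream —
#' the test stream's shadows use only test-stream history plus the
#' training-time calibration constants — so label or boundary leakage is
#' structurally impossible.
#'
#' @param spec an [ActivitySpec-class]; its seed slot is replaced by the
#'   entries of `seeds` (training) and `seeds + testSeedOffset` (testing).
#' @param learners character vector from the six learner kinds.
#' @param seeds integer vector of generator seeds.
#' @param config a [ShadowConfig-class].
#' @param modes testing modes to run.
#' @param strategies pre-processing strategies to compare.
#' @param haarWindow trailing window of the Haar baseline.
#' @param testSeedOffset offset separating test-stream seeds from training.
#' @return data.frame with one row per (strategy, learner, mode):
#'   seed-averaged accuracy, kappa (with its credibility band: >= 0.75
#'   high, >= 0.4 general, else low), macro-F and training time.
#' @export
compareStrategies <- function(spec, learners = c(BATCH_LEARNERS,
                                                 INCREMENTAL_LEARNERS),
                              seeds = 1:5, config = shadowConfig(),
                              modes = c("full_training", "train_then_test"),
                              strategies = c("original", "haar", "shadow"),
                              haarWindow = 8L, testSeedOffset = 500000L) {
  acc <- list()
  for (seed in seeds) {
    trainSpec <- spec; trainSpec@seed <- as.integer(seed)
    testSpec <- spec; testSpec@seed <- as.integer(seed + testSeedOffset)
    trainStream <- simulateActivityStream(trainSpec)
    testStream <- simulateActivityStream(testSpec)
    calibration <- calibrate(trainStream, config)
    for (strategy in strategies) {
      dtr <- .strategy_datasets(trainStream, strategy, config, calibration,
                                haarWindow)
      dte <- .strategy_datasets(testStream, strategy, config, calibration,
                                haarWindow)
      for (learner in learners) {
        for (mode in modes) {
          rep <- trainEval(dtr, learner, mode,
                           test = if (mode == "train_then_test") dte,
                           seed = seed)
          acc[[length(acc) + 1L]] <- data.frame(
            strategy = strategy, learner = learner, mode = mode,
            seed = seed, accuracy = rep@accuracy, kappa = rep@kappa,
            macro_f = rep@macroF, train_time = rep@trainTime,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  long <- do.call(rbind, acc)
  agg <- stats::aggregate(
    long[c("accuracy", "kappa", "macro_f", "train_time")],
    by = long[c("strategy", "learner", "mode")], FUN = mean)
  agg$kappa_band <- vapply(agg$kappa, .kappa_band, character(1))
  agg[order(agg$strategy, agg$learner, agg$mode), ]
}
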