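test_that("phi scaling maps H to [-1, 1] as printed", {
  expect_equal(phiFromHurst(0.5), 0)
  expect_equal(phiFromHurst(1.0), 1)
  expect_equal(phiFromHurst(0.2), -0.6)
  expect_error(phiFromHurst(0), "0, 1")
  expect_error(phiFromHurst(1.5), "0, 1")
})

test_that("uniform shadow follows the literal formula", {
  expect_equal(shadowUniform(c(2, 4, 6), phi = 0), 4)
  expect_equal(shadowUniform(c(2, 4, 6), phi = 0.5), 5)          # (1.5*6+4+2)/3
  expect_equal(shadowUniform(rep(7, 3), phi = 0), 7)
  # literal reading: denominator stays w when phi != 0 ...
  expect_equal(shadowUniform(rep(7, 3), phi = 1), (2 * 7 + 14) / 3)
  # ... unless normalization is requested
  expect_equal(shadowUniform(rep(7, 3), phi = 1, normalize = TRUE), 7)
  expect_error(shadowUniform(3, 0), "at least 2")
})

test_that("weighted shadow follows the literal formula", {
  expect_equal(shadowWeighted(c(1, 2, 3), phi = 0), 14 / 6)
  expect_equal(shadowWeighted(c(1, 2, 3), phi = 1), 23 / 6)
  expect_equal(shadowWeighted(rep(4, 5), phi = 0), 4)   # weights cancel
  expect_equal(shadowWeighted(rep(4, 5), phi = 0.3, normalize = TRUE), 4)
})

test_that("fixed-window uniform batch equals the worked w = 3 example", {
  s <- sensorSeries(matrix(as.numeric(1:10), ncol = 1))
  sh <- generateShadowBatch(s, fixedCalibration(s, 3L), static_config())
  expect_equal(shadowValues(sh)[, 1],
               c(NA, NA, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_identical(unknownMask(sh)[, 1],
                   c(TRUE, TRUE, rep(FALSE, 8)))
  expect_identical(colnames(shadowValues(sh)), "V1_shadow")
})

test_that("static uniform batch equals the brute-force trailing mean", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(40:200, 1)
    w <- sample(2:12, 1)
    x <- runif(n, -5, 5)
    s <- sensorSeries(cbind(x = x))
    sh <- generateShadowBatch(s, fixedCalibration(s, w), static_config())
    expect_equal(shadowValues(sh)[, 1], oracle_trailing_mean(x, w),
                 tolerance = 1e-12)
  }
})

test_that("constant features shadow to the constant wherever known", {
  s <- sensorSeries(cbind(c = rep(2.5, 300)))
  cal <- fixedCalibration(s, 8L)
  for (cfg in list(shadowConfig(), static_config(),
                   shadowConfig(weighting = "linear"))) {
    sh <- generateShadowBatch(s, cal, cfg)
    v <- shadowValues(sh)[, 1]
    expect_equal(v[!is.na(v)], rep(2.5, 293), tolerance = 1e-12)
  }
})

test_that("shadow output is bounded by its window when phi = 0", {
  set.seed(42)
  x <- rnorm(200)
  s <- sensorSeries(cbind(x = x))
  sh <- generateShadowBatch(s, fixedCalibration(s, 6L), static_config())
  v <- shadowValues(sh)[, 1]
  for (i in 6:200) {
    win <- x[(i - 5):i]
    expect_gte(v[i], min(win) - 1e-12)
    expect_lte(v[i], max(win) + 1e-12)
  }
})

test_that("linear weighting hugs a rising ramp tighter than uniform", {
  x <- as.numeric(1:50)
  s <- sensorSeries(cbind(x = x))
  cal <- fixedCalibration(s, 5L)
  u <- shadowValues(generateShadowBatch(s, cal, static_config()))[, 1]
  l <- shadowValues(generateShadowBatch(s, cal,
                                        static_config("linear")))[, 1]
  known <- which(!is.na(u))
  expect_true(all(abs(l[known] - x[known]) < abs(u[known] - x[known])))
})

test_that("streaming output equals batch output exactly, every config", {
  set.seed(43)
  x <- rnorm(300)
  s <- sensorSeries(cbind(x = x))
  configs <- list(
    static_config(),
    static_config("linear"),
    shadowConfig(),                                   # dynamic + phi
    shadowConfig(weighting = "linear", phiEnabled = FALSE),
    shadowConfig(dynamicWindow = FALSE)               # static + phi
  )
  for (cfg in configs) {
    cal <- if (cfg@dynamicWindow)
      calibrate(s, shadowConfig(calibrationSpan = 256L))
    else fixedCalibration(s, 8L)
    batch <- generateShadowBatch(s, cal, cfg)
    st <- shadowStream(cal, cfg)
    streamed <- vapply(x, function(v) shadowStreamPush(st, v, feature = "x"),
                       numeric(1))
    bv <- shadowValues(batch)[, 1]
    expect_identical(is.na(streamed), is.na(bv))
    expect_identical(streamed[!is.na(streamed)], bv[!is.na(bv)])
  }
})

test_that("per-feature streams are isolated from interleaving order", {
  set.seed(44)
  X <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- sensorSeries(X)
  cal <- fixedCalibration(s, 4L)
  cfg <- shadowConfig(dynamicWindow = TRUE, wMax = 16L)
  # row-ordered pushes
  st1 <- shadowStream(cal, cfg)
  out1 <- t(apply(X, 1, function(row) shadowStreamPush(st1, row)))
  # feature-by-feature pushes (different interleaving)
  st2 <- shadowStream(cal, cfg)
  out2 <- vapply(c("a", "b", "c"), function(f)
    vapply(X[, f], function(v) shadowStreamPush(st2, v, feature = f),
           numeric(1)), numeric(nrow(X)))
  expect_identical(unname(out1), unname(out2))
})

test_that("warm-up length follows the base window and push-after-close errors", {
  s <- sensorSeries(cbind(x = as.numeric(1:20)))
  cal <- fixedCalibration(s, 8L)
  st <- shadowStream(cal, static_config())
  out <- vapply(1:20, function(v) shadowStreamPush(st, as.numeric(v),
                                                   feature = 1L), numeric(1))
  expect_identical(which(is.na(out)), 1:7)
  shadowStreamClose(st)
  expect_error(shadowStreamPush(st, 1, feature = 1L), "closed")
})

test_that("dynamic windows grow with stream persistence", {
  mean_w <- function(H, seed) {
    x <- simulateFGN(H, 1024, seed)
    est <- fitHurstStart(x)
    row <- data.frame(
      h_start = hurstExponent(est), log_intercept = logIntercept(est),
      smoother = "moving_average",
      base_window = windowLengthForGrade(
        continuityGrade(hurstExponent(est))$grade))
    meanEmittedWindow(x, row, shadowConfig())
  }
  w_high <- mean(vapply(1:6, function(s) mean_w(0.9, s), numeric(1)))
  w_low <- mean(vapply(1:6, function(s) mean_w(0.3, s + 60), numeric(1)))
  expect_gt(w_high, w_low)
})

test_that("batch generation demands a covering calibration", {
  s <- sensorSeries(matrix(rnorm(40), ncol = 2))
  cal <- fixedCalibration(sensorSeries(matrix(rnorm(20), ncol = 1,
                                              dimnames = list(NULL, "V1"))),
                          4L)
  expect_error(generateShadowBatch(s, cal), "does not cover")
})
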