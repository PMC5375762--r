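test_that("cumulative deviates match the hand oracle and telescope to zero", {
  expect_equal(cumulativeDeviates(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(cumulativeDeviates(rep(3.7, 4)), rep(0, 4))
  set.seed(11)
  for (x in list(rnorm(50), rexp(33), cumsum(rnorm(100)))) {
    d <- cumulativeDeviates(x)
    expect_lt(abs(d[length(d)]), 1e-9 * max(1, max(abs(x))))
  }
  expect_error(cumulativeDeviates(numeric()), "at least one")
})

test_that("rescaled range matches the hand oracle and its invariances", {
  expect_equal(rescaledRange(c(1, 2, 3, 4)), 2 / sqrt(1.25))
  expect_true(is.na(rescaledRange(rep(2, 3))))   # degenerate signal
  set.seed(12)
  x <- rnorm(64)
  expect_equal(rescaledRange(3 * x), rescaledRange(x), tolerance = 1e-12)
  expect_equal(rescaledRange(x + 100), rescaledRange(x), tolerance = 1e-9)
  expect_error(rescaledRange(1), "at least two")
})

test_that("R/S fit recovers known Hurst exponents from fGn", {
  # small-n version of the recovery property; the acceptance test runs the
  # full n = 4096, 20-seed protocol
  for (H in c(0.3, 0.7, 0.9)) {
    est <- mean(vapply(1:8, function(s)
      hurstExponent(fitHurstStart(simulateFGN(H, 2048, s + 100))),
      numeric(1)))
    expect_lt(abs(est - H), 0.12)
  }
})

test_that("ramp input drives the Hurst estimate to its ceiling and noise sits near 0.5", {
  # a deterministic ramp is maximally persistent; the OLS slope carries a
  # small finite-size correction, so near-ceiling rather than exactly 1
  for (x in list(as.numeric(1:512), cumsum(as.numeric(1:512)))) {
    h_ramp <- hurstExponent(fitHurstStart(x))
    expect_gte(h_ramp, 0.99)
    expect_lte(h_ramp, 1)
  }
  est <- mean(vapply(1:10, function(s)
    hurstExponent(fitHurstStart(simulateFGN(0.5, 2048, s))), numeric(1)))
  expect_lt(abs(est - 0.5), 0.1)
})

test_that("fitHurstStart enforces its preconditions", {
  expect_error(fitHurstStart(rnorm(16)), "at least 32")
  expect_error(fitHurstStart(rnorm(100), scales = c(2, 8)), ">= 4")
  expect_error(fitHurstStart(rep(1, 64)), "usable scales|degenerate")
})

test_that("dynamic Hurst inverts the single-window power law pre-clamp", {
  set.seed(13)
  for (rep in 1:20) {
    w <- sample(8:64, 1)
    window <- rnorm(w)
    logC <- runif(1, -1, 0.2)
    rs <- rescaledRange(window)
    h_raw <- (log(rs) - logC) / log(w)
    h <- hurstDynamic(window, logC)
    if (h_raw > 0 && h_raw <= 1) {
      expect_equal(h, h_raw, tolerance = 1e-12)
      # re-evaluating the power law reproduces log(R/S) exactly
      expect_equal(logC + h * log(w), log(rs), tolerance = 1e-12)
    } else {
      expect_true(h > 0 && h <= 1)   # clamped
    }
  }
})

test_that("degenerate windows carry the previous exponent forward", {
  expect_equal(hurstDynamic(rep(5, 8), 0, previousH = 0.73), 0.73)
  expect_equal(hurstDynamic(rep(5, 8), 0), 0.5)
  expect_error(hurstDynamic(c(1, 2), 0), "at least 4")
})

test_that("persistent streams score higher dynamic H than anti-persistent", {
  mean_dyn <- function(H, seed) {
    x <- simulateFGN(H, 1024, seed)
    est <- fitHurstStart(x)
    hs <- vapply(32:1024, function(i)
      hurstDynamic(x[(i - 31):i], logIntercept(est)), numeric(1))
    mean(hs)
  }
  h_high <- mean(vapply(1:5, function(s) mean_dyn(0.9, s), numeric(1)))
  h_low <- mean(vapply(1:5, function(s) mean_dyn(0.3, s + 50), numeric(1)))
  expect_gt(h_high, h_low)
})

test_that("continuity grades partition (0, 1] per the printed intervals", {
  expect_identical(continuityGrade(0.9), list(grade = 5L,
                                              intensity = "Very strong"))
  expect_identical(continuityGrade(0.52)$grade, 1L)
  expect_identical(continuityGrade(0.52)$intensity, "Very weak")
  # boundary H = 0.50 belongs to (0.45, 0.50]
  expect_identical(continuityGrade(0.5)$grade, -1L)
  # totality and upper-inclusive boundaries
  for (H in c(1e-9, 0.2, 0.200001, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75,
              0.8, 0.800001, 1)) {
    g <- continuityGrade(H)
    expect_true(g$grade %in% c(-5:-1, 1:5))
  }
  expect_identical(continuityGrade(0.2)$grade, -5L)
  expect_identical(continuityGrade(0.8)$grade, 4L)
  expect_identical(continuityGrade(1)$grade, 5L)
  # non-decreasing in H on the persistent side
  hs <- seq(0.500001, 1, length.out = 200)
  gs <- vapply(hs, function(h) continuityGrade(h)$grade, integer(1))
  expect_true(all(diff(gs) >= 0))
  expect_error(continuityGrade(0), "0, 1")
  expect_error(continuityGrade(1.2), "0, 1")
})

test_that("grade-to-window lookup follows magnitude and clamps", {
  expect_identical(windowLengthForGrade(5), 128L)
  expect_identical(windowLengthForGrade(-5), 128L)
  expect_identical(windowLengthForGrade(1), 8L)
  expect_identical(windowLengthForGrade(5, wMax = 64L), 64L)
  expect_identical(windowLengthForGrade(1, mapping = c(2, 4, 8, 16, 32),
                                        wMin = 4L), 4L)
  # monotone mapping gives non-decreasing lengths in |grade|
  lens <- vapply(1:5, windowLengthForGrade, integer(1))
  expect_true(all(diff(lens) >= 0))
  expect_error(windowLengthForGrade(6), "magnitude")
  expect_error(windowLengthForGrade(2, mapping = c(8, NA, 32, 64, 128)),
               "mapping")
})
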