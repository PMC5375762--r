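# Start-up characterization: three questions are asked of the calibration
# span of every feature — is it stationary, does it trend, is it a bare
# random walk — and the answers pick the smoother used for shadow
# generation. The unit-root test is an augmented Dickey-Fuller regression
# with constant (no package in the stack provides one); the trend test is
# Mann-Kendall, realized as Kendall's tau against the time index; the
# random-walk test asks whether the first differences are serially
# uncorrelated once the series failed the stationarity test.

# Critical values of the Dickey-Fuller tau_mu statistic (regression with
# constant), Fuller (1976) / Banerjee et al. (1993); rows are sample sizes,
# columns lower-tail probabilities.
.ADF_N <- c(25, 50, 100, 250, 500, Inf)
.ADF_P <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.ADF_TABLE <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60
), nrow = 6, byrow = TRUE)

# ADF regression: diff(y)_t ~ 1 + y_{t-1} + lagged diffs; returns the
# t-statistic on y_{t-1} and its interpolated lower-tail p-value.
.adf_stat <- function(y, lags = NULL) {
  n <- length(y)
  if (is.null(lags)) lags <- trunc((n - 1)^(1 / 3))
  dy <- diff(y)
  k <- lags + 1L
  nd <- length(dy)
  z <- stats::embed(dy, k)
  resp <- z[, 1L]
  ylag <- y[k:(n - 1L)]
  X <- if (k > 1L) cbind(ylag, z[, 2:k, drop = FALSE]) else cbind(ylag)
  fit <- stats::lm.fit(cbind(1, X), resp)
  res <- fit$residuals
  dfree <- length(resp) - ncol(X) - 1L
  s2 <- sum(res^2) / dfree
  XtX <- crossprod(cbind(1, X))
  vc <- tryCatch(s2 * solve(XtX), error = function(e) NULL)
  if (is.null(vc)) return(list(stat = NA_real_, p = NA_real_))
  tstat <- fit$coefficients[2L] / sqrt(vc[2L, 2L])
  # bilinear interpolation of the tau_mu table, clamped at its edges
  row <- vapply(seq_along(.ADF_P), function(j)
    stats::approx(.ADF_N[-6], .ADF_TABLE[-6, j], xout = min(n, 500),
                  rule = 2)$y, numeric(1))
  if (n > 500) row <- .ADF_TABLE[6, ]
  p <- stats::approx(row, .ADF_P, xout = tstat, rule = 2)$y
  list(stat = unname(tstat), p = p)
}

#' Stationarity test (unit root)
#'
#' Augmented Dickey-Fuller regression with constant: the segment is called
#' stationary when the unit-root null is rejected at `alpha`. Constant
#' (zero-variance) segments are treated as stationary by decision rule.
#'
#' @param segment numeric vector, length >= 32.
#' @param alpha significance level, default 0.05.
#' @return logical: TRUE when stationary.
#' @examples
#' testStationarity(rnorm(256))          # TRUE
#' testStationarity(cumsum(rnorm(256)))  # FALSE
#' @export
testStationarity <- function(segment, alpha = 0.05) {
  if (length(segment) < 32L) stop("segment too short (need >= 32)")
  if (stats::var(segment) == 0) return(TRUE)
  a <- .adf_stat(segment)
  isTRUE(a$p < alpha)
}

#' Monotone-trend test (Mann-Kendall, autocorrelation-corrected)
#'
#' The Mann-Kendall S statistic (Kendall's tau numerator against the time
#' index), two-sided at `alpha`, with the Hamed-Rao variance correction:
#' the null variance is inflated by the effective-sample-size factor
#' computed from the significant lags of the rank autocorrelation, so that
#' serially correlated but trend-free segments — e.g. quasi-periodic
#' activity bouts — are not spuriously flagged. Constant segments have no
#' trend.
#'
#' @inheritParams testStationarity
#' @return logical: TRUE when a monotone trend is detected.
#' @export
testTrend <- function(segment, alpha = 0.05) {
  n <- length(segment)
  if (n < 32L) stop("segment too short (need >= 32)")
  if (stats::var(segment) == 0) return(FALSE)
  # entries [i, j] with i > j are x_later - x_earlier
  S <- sum(sign(outer(segment, segment, "-"))[lower.tri(diag(n))])
  v0 <- n * (n - 1) * (2 * n + 5) / 18
  rk <- rank(segment)
  maxLag <- min(n - 3L, floor(n / 4))
  ac <- stats::acf(rk, lag.max = maxLag, plot = FALSE)$acf[-1]
  sig <- which(abs(ac) > stats::qnorm(1 - 0.05 / 2) / sqrt(n))
  corr <- 1
  if (length(sig)) {
    k <- sig
    corr <- 1 + 2 / (n * (n - 1) * (n - 2)) *
      sum((n - k) * (n - k - 1) * (n - k - 2) * ac[k])
  }
  vs <- v0 * max(corr, 1e-6)
  z <- (S - sign(S)) / sqrt(vs)
  isTRUE(2 * stats::pnorm(-abs(z)) < alpha)
}

#' Random-walk test
#'
#' A segment is called a bare random walk when it is non-stationary AND its
#' first differences show no significant lag-1 autocorrelation (Ljung-Box at
#' `alpha`) — i.e., the increments look like unforecastable noise.
#'
#' @inheritParams testStationarity
#' @return logical: TRUE when the segment behaves like a random walk.
#' @export
testRandomWalk <- function(segment, alpha = 0.05) {
  if (length(segment) < 32L) stop("segment too short (need >= 32)")
  if (stats::var(segment) == 0) return(FALSE)
  if (testStationarity(segment, alpha)) return(FALSE)
  lb <- stats::Box.test(diff(segment), lag = 1L, type = "Ljung-Box")
  isTRUE(lb$p.value >= alpha)
}

#' Choose the smoother from the characterization flags
#'
#' IF-THEN-ELSE rule table: a trending segment is detrended before moving
#' averaging; a bare random walk gets the naive last-value carry (its own
#' history is the best forecast); everything else — in particular the
#' stationary, trend-free streams typical of repeated activities — gets the
#' plain moving average.
#'
#' @param stationary,trend,randomWalk logical flags from the three tests.
#' @return one of `"moving_average"`, `"detrend_then_moving_average"`,
#'   `"naive_last_value"`.
#' @examples
#' chooseSmoother(TRUE, FALSE, FALSE)  # moving_average
#' @export
chooseSmoother <- function(stationary, trend, randomWalk) {
  if (isTRUE(trend)) return("detrend_then_moving_average")
  if (isTRUE(randomWalk)) return("naive_last_value")
  "moving_average"
}

#' Calibrate shadow generation on the initial samples
#'
#' For every feature of the stream, over the calibration span (the first
#' `config@calibrationSpan` samples; by default min(1000, ceiling(0.1 N)),
#' raised to 128 so the R/S fit has at least three scales): run the
#' stationarity, trend and random-walk tests, choose the smoother, fit the
#' start-up Hurst exponent and log-intercept, and map its continuity grade
#' to the base window length. Deterministic given (series, config).
#'
#' @param series a [SensorSeries-class] with at least 128 samples.
#' @param config a [ShadowConfig-class].
#' @return a [CalibrationResult-class].
#' @examples
#' s <- simulateActivityStream(defaultActivitySpec(segmentLength = 300L))
#' calibrationTable(calibrate(s))
#' @export
calibrate <- function(series, config = shadowConfig()) {
  validObject(config)
  n <- nSamples(series)
  span <- config@calibrationSpan
  if (is.na(span)) span <- min(1000L, max(128L, as.integer(ceiling(0.1 * n))))
  if (span > n)
    stop("calibration span (", span, ") exceeds the series length (", n, ")")
  if (span < 64L) stop("calibration span must be at least 64 samples")
  rows <- lapply(seq_len(nFeatures(series)), function(j) {
    seg <- series@values[seq_len(span), j]
    st <- testStationarity(seg, config@alpha)
    tr <- testTrend(seg, config@alpha)
    rw <- testRandomWalk(seg, config@alpha)
    est <- fitHurstStart(seg)
    grade <- continuityGrade(est@H)$grade
    data.frame(
      feature = featureNames(series)[j],
      h_start = est@H,
      log_intercept = est@logIntercept,
      smoother = chooseSmoother(st, tr, rw),
      base_window = windowLengthForGrade(grade, config@gradeMapping,
                                         config@wMin, config@wMax),
      stationary = st, trend = tr, random_walk = rw,
      stringsAsFactors = FALSE)
  })
  new("CalibrationResult", table = do.call(rbind, rows),
      span = as.integer(span), config = config)
}
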