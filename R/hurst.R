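# Rescaled-range (R/S) statistics and Hurst-exponent machinery.
#
# The estimator follows classic Hurst/Mandelbrot R/S analysis: for a block
# of length w, form the cumulative deviations from the block mean, take
# their range, and divide by the population (1/n) standard deviation of the
# block. Averaging R/S over non-overlapping blocks at several block lengths
# realizes the expectation in E[R/S](w) = C w^H, and an OLS fit of
# log(R/S) on log(w) yields H (slope) and log C (intercept).

#' Cumulative mean-deviation series
#'
#' For a segment r_1..r_n with mean mu, returns the running sums
#' \eqn{\delta_t = \sum_{i \le t} (r_i - \mu)}. The last element is zero up
#' to rounding (the deviations telescope).
#'
#' @param segment numeric vector, length >= 1.
#' @return numeric vector of the same length.
#' @examples
#' cumulativeDeviates(c(1, 2, 3))  # -1 -1 0
#' @export
cumulativeDeviates <- function(segment) {
  if (length(segment) < 1L) stop("segment must contain at least one value")
  cumsum(segment - mean(segment))
}

#' Rescaled range of a segment
#'
#' Range of the cumulative mean-deviation series divided by the population
#' standard deviation (the divisor is n, not n-1, matching the defining
#' formula). The statistic is invariant to translation and to positive
#' rescaling of the segment.
#'
#' @param segment numeric vector, length >= 2.
#' @return a positive number, or `NA_real_` for a zero-variance
#'   (degenerate) segment, in which case the caller decides the fallback.
#' @examples
#' rescaledRange(c(1, 2, 3, 4))  # 2 / sqrt(1.25)
#' @export
rescaledRange <- function(segment) {
  n <- length(segment)
  if (n < 2L) stop("segment must contain at least two values")
  delta <- cumsum(segment - mean(segment))
  s <- sqrt(sum((segment - mean(segment))^2) / n)
  if (s == 0) return(NA_real_)
  (max(delta) - min(delta)) / s
}

#' Fit the start-up Hurst exponent by R/S analysis
#'
#' Partitions the series into non-overlapping blocks at each scale, averages
#' the rescaled range over blocks, and fits log(R/S) against log(scale) by
#' ordinary least squares. The slope, clamped to (0, 1], is the Hurst
#' estimate; the intercept log C is kept for the dynamic-exponent inversion.
#'
#' @param series numeric vector, length >= 32.
#' @param scales optional integer vector of block lengths (each >= 4,
#'   strictly increasing). Defaults to powers of two from 8 up to
#'   floor(n/4); at least 3 usable scales are required.
#' @return a [HurstEstimate-class] object.
#' @examples
#' set.seed(1)
#' fitHurstStart(rnorm(1024))  # H near 0.5 for white noise
#' @export
fitHurstStart <- function(series, scales = NULL) {
  n <- length(series)
  if (n < 32L) stop("need at least 32 samples to fit the Hurst exponent")
  if (is.null(scales)) {
    scales <- 2^(3:floor(log2(n / 4)))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 4L)) stop("every scale must be >= 4")
  mean_rs <- vapply(scales, function(w) {
    nb <- n %/% w
    if (nb < 1L) return(NA_real_)
    rs <- vapply(seq_len(nb), function(b) {
      rescaledRange(series[((b - 1L) * w + 1L):(b * w)])
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    if (!length(rs)) NA_real_ else mean(rs)
  }, numeric(1))
  ok <- is.finite(mean_rs) & mean_rs > 0
  if (sum(ok) < 3L)
    stop("fewer than 3 usable scales: series too short or degenerate")
  fit <- stats::lsfit(log(scales[ok]), log(mean_rs[ok]))
  h <- unname(fit$coefficients[2L])
  new("HurstEstimate",
      H = min(max(h, .Machine$double.eps), 1),
      logIntercept = unname(fit$coefficients[1L]),
      scales = scales[ok], rsValues = mean_rs[ok], nPoints = as.integer(n))
}

#' Window-local (dynamic) Hurst exponent
#'
#' Inverts the single-window power law: with the calibration intercept
#' log C fixed, \eqn{H = (\log(R/S)_w - \log C) / \log(w)}, clamped to
#' (0, 1]. For a degenerate (zero-variance) window the previous exponent is
#' carried forward, so a constant activity degrades gracefully to a plain
#' moving average.
#'
#' @param window numeric vector, the current trailing window (length >= 4).
#' @param logInterceptValue the calibration regression intercept log C.
#' @param previousH fallback exponent for degenerate windows (default 0.5,
#'   which makes the phi boost vanish).
#' @return the clamped dynamic Hurst exponent.
#' @examples
#' hurstDynamic(c(1, 3, 2, 5, 4, 6), logInterceptValue = 0)
#' @export
hurstDynamic <- function(window, logInterceptValue, previousH = 0.5) {
  if (length(window) < 4L) stop("window must contain at least 4 values")
  rs <- rescaledRange(window)
  if (!is.finite(rs) || rs <= 0) return(previousH)
  h <- (log(rs) - logInterceptValue) / log(length(window))
  min(max(h, .Machine$double.eps), 1)
}

.GRADE_BREAKS <- c(0, 0.20, 0.25, 0.35, 0.45, 0.50, 0.55, 0.65, 0.75, 0.80, 1)
.GRADE_VALUES <- c(-5L, -4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L, 5L)
.GRADE_LABELS <- c("Very strong", "Strong", "Normal strong", "Weak",
                   "Very weak", "Very weak", "Weak", "Normal strong",
                   "Strong", "Very strong")

#' Continuity-intensity grade of a Hurst exponent
#'
#' Maps H to the signed continuity grade: positive grades 1..5 for
#' persistent series (H above 0.5), negative grades -1..-5 for
#' anti-persistent ones, with intensity growing as H moves away from 0.5.
#' Intervals are lower-exclusive/upper-inclusive, so H = 0.50 falls in
#' (0.45, 0.50] and grades -1.
#'
#' @param H numeric scalar in (0, 1].
#' @return list with integer `grade` (in -5..-1, 1..5) and character
#'   `intensity` label.
#' @examples
#' continuityGrade(0.9)   # grade 5, "Very strong"
#' continuityGrade(0.52)  # grade 1, "Very weak"
#' @export
continuityGrade <- function(H) {
  if (!is.finite(H) || H <= 0 || H > 1)
    stop("H must lie in (0, 1]")
  i <- findInterval(H, .GRADE_BREAKS, left.open = TRUE, rightmost.closed = TRUE)
  list(grade = .GRADE_VALUES[i], intensity = .GRADE_LABELS[i])
}

#' Window length for a continuity grade
#'
#' Looks up the trailing-window length for the magnitude of the grade
#' (persistent and anti-persistent series of equal intensity get the same
#' window) and clamps it to [wMin, wMax]. The mapping must be
#' non-decreasing: the stronger the long-range memory, the longer the
#' window.
#'
#' @param grade integer in -5..-1 or 1..5, from [continuityGrade()].
#' @param mapping numeric length 5, window length per grade magnitude 1..5.
#' @param wMin,wMax clamp bounds.
#' @return integer window length.
#' @examples
#' windowLengthForGrade(5)   # 128 under the default mapping
#' windowLengthForGrade(-5)  # same: magnitude rule
#' @export
windowLengthForGrade <- function(grade, mapping = c(8, 16, 32, 64, 128),
                                 wMin = 2L, wMax = 512L) {
  m <- abs(as.integer(grade))
  if (m < 1L || m > 5L) stop("grade magnitude must be in 1..5")
  if (length(mapping) != 5L || anyNA(mapping))
    stop("mapping must provide window lengths for magnitudes 1..5")
  as.integer(min(max(mapping[m], wMin), wMax))
}
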