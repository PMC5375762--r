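# Shadow-feature value generation. A shadow feature is a smoothed companion
# of an original sensor channel, computed over a trailing window whose
# length tracks the window-local Hurst exponent (long-range-memory
# strength) and whose newest sample is boosted by the phi scaling factor.

#' Phi scaling factor from a Hurst exponent
#'
#' \eqn{\phi = (|H| - 0.5) / 0.5}, in [-1, 1]. Memoryless series (H = 0.5)
#' get no boost; strongly persistent series weight the newest sample up to
#' twice; anti-persistent series damp it.
#'
#' @param H Hurst exponent in (0, 1].
#' @return numeric in [-1, 1].
#' @examples
#' phiFromHurst(0.5)  # 0
#' phiFromHurst(1.0)  # 1
#' @export
phiFromHurst <- function(H) {
  if (!is.finite(H) || H <= 0 || H > 1) stop("H must lie in (0, 1]")
  (abs(H) - 0.5) / 0.5
}

#' Uniform-weight shadow value
#'
#' \eqn{((\phi + 1) r_i + r_{i-1} + \dots + r_{i-w+1}) / w}: the trailing
#' mean with the newest sample scaled by (phi + 1). The denominator stays w
#' even when phi is nonzero (the printed-formula reading); set
#' `normalize = TRUE` to fold the boost into the denominator and keep the
#' output a weighted mean.
#'
#' @param window numeric vector, oldest to newest, length >= 2.
#' @param phi scaling factor in [-1, 1].
#' @param normalize logical, off by default.
#' @return numeric scalar.
#' @examples
#' shadowUniform(c(2, 4, 6), phi = 0)    # 4
#' shadowUniform(c(2, 4, 6), phi = 0.5)  # 5
#' @export
shadowUniform <- function(window, phi = 0, normalize = FALSE) {
  w <- length(window)
  if (w < 2L) stop("window must contain at least 2 values")
  denom <- if (normalize) w + phi else w
  ((phi + 1) * window[w] + sum(window[-w])) / denom
}

#' Linearly weighted shadow value
#'
#' Weights decay linearly into the past: the newest sample has weight
#' \eqn{(\phi + 1) w}, the next w - 1, down to 1 for the oldest; the
#' denominator is the weight total \eqn{w (w + 1) / 2} (again left
#' unchanged by phi unless `normalize = TRUE`).
#'
#' @inheritParams shadowUniform
#' @return numeric scalar.
#' @examples
#' shadowWeighted(c(1, 2, 3), phi = 0)  # 14/6
#' shadowWeighted(c(1, 2, 3), phi = 1)  # 23/6
#' @export
shadowWeighted <- function(window, phi = 0, normalize = FALSE) {
  w <- length(window)
  if (w < 2L) stop("window must contain at least 2 values")
  wt <- seq_len(w)
  num <- (phi + 1) * w * window[w] + sum(wt[-w] * window[-w])
  denom <- w * (w + 1) / 2 + if (normalize) phi * w else 0
  num / denom
}

# One smoothing step on the current trailing window (oldest..newest).
# Dispatches on the calibrated smoother; weighting applies to the
# moving-average family, naive ignores phi, detrending removes the
# within-window OLS line (anchored at the newest slot) before smoothing.
.smooth_step <- function(window, smoother, weighting, phi, normalize) {
  L <- length(window)
  if (smoother == "naive_last_value") return(window[L - 1L])
  if (smoother == "detrend_then_moving_average" && L >= 3L) {
    pos <- seq_len(L)
    slope <- stats::cov(pos, window) / stats::var(pos)
    window <- window - slope * (pos - L)
  }
  if (smoother == "weighted_moving_average" || weighting == "linear")
    shadowWeighted(window, phi, normalize)
  else
    shadowUniform(window, phi, normalize)
}

#' Generate shadow features for a whole series (batch)
#'
#' For each feature: the first \eqn{w_{start} - 1} output slots are marked
#' unknown (the trailing window is not yet full). From slot
#' \eqn{w_{start}} on, at every step the window-local Hurst exponent is
#' re-estimated over the current window (when dynamic windows are enabled
#' and the window holds at least 4 values), phi is derived from it, the
#' calibrated smoother emits the shadow value, and the window length for
#' the NEXT step is looked up from the continuity grade — so every emitted
#' value is a pure function of already-seen data. When the window shrinks
#' the oldest values are dropped at once; when it grows it refills one
#' sample per step.
#'
#' @param series a [SensorSeries-class].
#' @param calibration a [CalibrationResult-class] covering every feature of
#'   `series` (see [calibrate()]).
#' @param config a [ShadowConfig-class].
#' @return a [ShadowSeries-class], same shape as `series`, feature names
#'   suffixed with `"_shadow"`.
#' @examples
#' s <- sensorSeries(matrix(as.numeric(1:10), ncol = 1))
#' cal <- fixedCalibration(s, window = 3L)
#' shadowValues(generateShadowBatch(s, cal,
#'   shadowConfig(dynamicWindow = FALSE, phiEnabled = FALSE)))
#' @export
generateShadowBatch <- function(series, calibration,
                                config = shadowConfig()) {
  validObject(config)
  tab <- calibration@table
  feats <- featureNames(series)
  if (!all(feats %in% tab$feature))
    stop("calibration does not cover feature(s): ",
         paste(setdiff(feats, tab$feature), collapse = ", "))
  n <- nSamples(series)
  m <- nFeatures(series)
  vals <- matrix(NA_real_, n, m)
  mask <- matrix(FALSE, n, m)
  for (j in seq_len(m)) {
    row <- tab[match(feats[j], tab$feature), ]
    x <- series@values[, j]
    res <- .shadow_column(x, row, config)
    vals[, j] <- res$values
    mask[, j] <- res$mask
  }
  vals[mask] <- 0  # placeholder under the mask; accessors return NA there
  colnames(vals) <- paste0(feats, SHADOW_SUFFIX)
  colnames(mask) <- colnames(vals)
  new("ShadowSeries", values = vals, unknownMask = mask)
}

# Batch path: direct indexed loop over the full vector (the streaming path
# in stream.R is an independent buffer state machine; tests assert exact
# slot-for-slot agreement).
.shadow_column <- function(x, calRow, config) {
  n <- length(x)
  wStart <- as.integer(min(max(calRow$base_window, config@wMin), config@wMax))
  out <- rep(NA_real_, n)
  mask <- rep(TRUE, n)
  if (n < wStart) return(list(values = out, mask = mask))
  hPrev <- calRow$h_start
  logC <- calRow$log_intercept
  wTarget <- wStart
  L <- wStart - 1L
  for (i in wStart:n) {
    L <- min(L + 1L, wTarget)
    win <- x[(i - L + 1L):i]
    if (config@dynamicWindow && L >= 4L)
      hPrev <- hurstDynamic(win, logC, previousH = hPrev)
    phi <- if (config@phiEnabled) phiFromHurst(hPrev) else 0
    out[i] <- .smooth_step(win, calRow$smoother, config@weighting, phi,
                           config@normalizeDenominator)
    mask[i] <- FALSE
    if (config@dynamicWindow)
      wTarget <- windowLengthForGrade(continuityGrade(hPrev)$grade,
                                      config@gradeMapping,
                                      config@wMin, config@wMax)
  }
  list(values = out, mask = mask)
}

#' Fixed calibration for a known window length
#'
#' Convenience constructor used when the Hurst-driven calibration is not
#' wanted: every feature gets a plain moving average with the given window
#' and a neutral Hurst state (H = 0.5, log C = 0), so with
#' `dynamicWindow = FALSE`, `phiEnabled = FALSE` the shadow is exactly the
#' trailing mean.
#'
#' @param series a [SensorSeries-class].
#' @param window integer window length, >= 2.
#' @param smoother smoother label, default "moving_average".
#' @return a [CalibrationResult-class].
#' @export
fixedCalibration <- function(series, window,
                             smoother = "moving_average") {
  stopifnot(window >= 2L, smoother %in% SMOOTHERS)
  feats <- featureNames(series)
  new("CalibrationResult",
      table = data.frame(
        feature = feats, h_start = 0.5, log_intercept = 0,
        smoother = smoother, base_window = as.integer(window),
        stationary = TRUE, trend = FALSE, random_walk = FALSE,
        stringsAsFactors = FALSE),
      span = 0L, config = NULL)
}

#' Mean emitted window length of a shadow run
#'
#' Replays the dynamic-window schedule of [generateShadowBatch()] on one
#' feature and returns the mean effective window length over all emitting
#' steps — the diagnostic used to check that persistent streams earn longer
#' windows than anti-persistent ones.
#'
#' @param x numeric vector (one feature).
#' @param calRow one row of a calibration table (see [calibrate()]).
#' @param config a [ShadowConfig-class].
#' @return mean window length over the emitted slots.
#' @export
meanEmittedWindow <- function(x, calRow, config = shadowConfig()) {
  n <- length(x)
  wStart <- as.integer(min(max(calRow$base_window, config@wMin), config@wMax))
  if (n < wStart) stop("series shorter than the warm-up window")
  hPrev <- calRow$h_start
  wTarget <- wStart
  L <- wStart - 1L
  lens <- numeric(n - wStart + 1L)
  for (i in wStart:n) {
    L <- min(L + 1L, wTarget)
    win <- x[(i - L + 1L):i]
    if (config@dynamicWindow && L >= 4L)
      hPrev <- hurstDynamic(win, calRow$log_intercept, previousH = hPrev)
    lens[i - wStart + 1L] <- L
    if (config@dynamicWindow)
      wTarget <- windowLengthForGrade(continuityGrade(hPrev)$grade,
                                      config@gradeMapping,
                                      config@wMin, config@wMax)
  }
  mean(lens)
}
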