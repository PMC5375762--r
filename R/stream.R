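# One-pass streaming shadow generation: constant memory per feature (the
# trailing buffer never exceeds the current target window length). The
# state machine here is written independently of the batch loop in
# shadow.R; the test suite asserts exact slot-for-slot agreement.

#' Open a streaming shadow generator
#'
#' Initializes per-feature window state from a calibration: target window
#' length, empty buffer, start-up Hurst exponent and its log-intercept.
#' Subsequent [shadowStreamPush()] calls mutate the returned object's
#' state environment.
#'
#' @param calibration a [CalibrationResult-class].
#' @param config a [ShadowConfig-class].
#' @return a [ShadowStream-class].
#' @examples
#' s <- sensorSeries(matrix(as.numeric(1:10), ncol = 1))
#' st <- shadowStream(fixedCalibration(s, 3L),
#'                    shadowConfig(dynamicWindow = FALSE, phiEnabled = FALSE))
#' sapply(1:10, function(v) shadowStreamPush(st, v, feature = 1L))
#' @export
shadowStream <- function(calibration, config = shadowConfig()) {
  validObject(config)
  tab <- calibration@table
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$closed <- FALSE
  e$features <- tab$feature
  e$state <- lapply(seq_len(nrow(tab)), function(j) {
    wStart <- as.integer(min(max(tab$base_window[j], config@wMin),
                             config@wMax))
    fe <- new.env(parent = emptyenv())
    fe$i <- 0L
    fe$wStart <- wStart
    fe$wTarget <- wStart
    fe$buffer <- numeric(0)
    fe$H <- tab$h_start[j]
    fe$phi <- if (config@phiEnabled) phiFromHurst(tab$h_start[j]) else 0
    fe$logC <- tab$log_intercept[j]
    fe$smoother <- tab$smoother[j]
    fe
  })
  names(e$state) <- tab$feature
  new("ShadowStream", state = e)
}

#' Push one value (or one row) into a shadow stream
#'
#' Advances the per-feature window state by one sample and returns the
#' shadow value, or `NA` (the unknown marker) while the feature is still in
#' its warm-up. Features are fully independent: interleaving pushes across
#' features in any order leaves each feature's outputs unchanged.
#'
#' @param stream a [ShadowStream-class].
#' @param value numeric scalar (with `feature` named) or a full row of
#'   length M (all features, in calibration order).
#' @param feature feature index or name; may be omitted when `value` is a
#'   full row.
#' @return numeric scalar, or numeric vector of length M for a row push;
#'   `NA` marks warm-up slots.
#' @export
shadowStreamPush <- function(stream, value, feature = NULL) {
  e <- stream@state
  if (e$closed) stop("push after the stream was closed")
  if (is.null(feature)) {
    if (length(value) != length(e$state))
      stop("row push needs one value per calibrated feature")
    return(vapply(seq_along(e$state),
                  function(j) .stream_push_one(e$state[[j]], value[j],
                                               e$config),
                  numeric(1)))
  }
  if (length(value) != 1L) stop("per-feature push takes a scalar")
  fe <- e$state[[feature]]
  if (is.null(fe)) stop("unknown feature: ", feature)
  .stream_push_one(fe, value, e$config)
}

.stream_push_one <- function(fe, value, config) {
  fe$i <- fe$i + 1L
  # grow by one sample, truncating the oldest if over the target length
  buf <- c(fe$buffer, value)
  L <- length(buf)
  if (L > fe$wTarget) {
    buf <- buf[(L - fe$wTarget + 1L):L]
    L <- fe$wTarget
  }
  fe$buffer <- buf
  if (fe$i < fe$wStart) return(NA_real_)
  if (config@dynamicWindow && L >= 4L) {
    fe$H <- hurstDynamic(buf, fe$logC, previousH = fe$H)
    fe$phi <- if (config@phiEnabled) phiFromHurst(fe$H) else 0
  }
  out <- .smooth_step(buf, fe$smoother, config@weighting, fe$phi,
                      config@normalizeDenominator)
  if (config@dynamicWindow)
    fe$wTarget <- windowLengthForGrade(continuityGrade(fe$H)$grade,
                                       config@gradeMapping,
                                       config@wMin, config@wMax)
  out
}

#' Close a shadow stream
#'
#' Marks the stream closed; any further push raises an error.
#'
#' @param stream a [ShadowStream-class].
#' @return invisibly, the per-feature final window lengths.
#' @export
shadowStreamClose <- function(stream) {
  stream@state$closed <- TRUE
  invisible(vapply(stream@state$state, function(fe) fe$wTarget, numeric(1)))
}
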