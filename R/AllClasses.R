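#' @import methods
NULL

SHADOW_SUFFIX <- "_shadow"

#' Multivariate sensor time series
#'
#' \code{SensorSeries} is the container for an ordered multivariate motion
#' stream: an N x M numeric matrix of feature values (rows are time-ordered
#' instances, columns are sensor channels such as the x/y/z axes of an
#' accelerometer), a timestamp vector, and an optional per-row activity
#' label. Timestamps may be wall-clock seconds or plain sample indices; the
#' shadow-feature machinery is order-based and only uses them for alignment
#' and rate inference.
#'
#' @slot values numeric matrix, N rows (instances) by M columns (features).
#' @slot timestamps numeric vector of length N, strictly increasing.
#' @slot labels character vector of length N (activity class per row) or
#'   length 0 when the stream is unlabeled.
#' @slot samplingRate numeric of length 1 (Hz) or length 0 when unknown.
#'
#' @seealso [sensorSeries()] for the user-facing constructor,
#'   [readSensorCSV()] to build one from disk.
#' @exportClass SensorSeries
setClass("SensorSeries",
  representation(
    values = "matrix",
    timestamps = "numeric",
    labels = "character",
    samplingRate = "numeric"
  )
)

setValidity("SensorSeries", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) < 1L) msgs <- c(msgs, "need at least one row")
  if (ncol(v) < 1L) msgs <- c(msgs, "need at least one feature column")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "feature names must be present and unique")
  if (any(endsWith(colnames(v) %||% character(), SHADOW_SUFFIX)))
    msgs <- c(msgs, sprintf(
      "feature names must not end in the reserved suffix '%s'", SHADOW_SUFFIX))
  if (length(object@timestamps) != nrow(v))
    msgs <- c(msgs, "timestamps must have one entry per row")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (length(object@labels) > 0L && length(object@labels) != nrow(v))
    msgs <- c(msgs, "labels, when present, must have one entry per row")
  if (length(object@samplingRate) > 1L)
    msgs <- c(msgs, "samplingRate must be length 0 or 1")
  if (length(msgs)) msgs else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shadow-feature series with warm-up mask
#'
#' Holds the smoothed companion series for every feature of a
#' \code{SensorSeries}. The first \eqn{w_{start} - 1} slots of each column
#' are not computable (the trailing window is not yet full); they are marked
#' unknown and serialized as the literal token \code{"?"}.
#'
#' @slot values numeric matrix, same shape as the source series.
#' @slot unknownMask logical matrix; \code{TRUE} marks warm-up slots.
#'
#' @exportClass ShadowSeries
setClass("ShadowSeries",
  representation(values = "matrix", unknownMask = "matrix")
)

setValidity("ShadowSeries", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@unknownMask)))
    msgs <- c(msgs, "values and unknownMask must have identical dimensions")
  if (!is.logical(object@unknownMask))
    msgs <- c(msgs, "unknownMask must be logical")
  for (j in seq_len(ncol(object@unknownMask))) {
    m <- object@unknownMask[, j]
    k <- sum(m)
    if (k > 0L && !all(which(m) == seq_len(k))) {
      msgs <- c(msgs, "unknown slots must form a leading run in each column")
      break
    }
  }
  known <- !object@unknownMask
  if (any(known) && !all(is.finite(object@values[known])))
    msgs <- c(msgs, "values must be finite wherever the mask is FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Rescaled-range Hurst fit
#'
#' Result of fitting the rescaled-range power law
#' \eqn{E[R/S](w) = C w^H} by ordinary least squares of \eqn{\log(R/S)} on
#' \eqn{\log(w)} over a set of block lengths. The slope is the Hurst
#' exponent estimate (clamped to (0, 1]); the intercept is \eqn{\log C} and
#' is reused when single windows are inverted for the dynamic exponent.
#'
#' @slot H numeric, the Hurst estimate in (0, 1].
#' @slot logIntercept numeric, the regression intercept \eqn{\log C}.
#' @slot scales integer vector of block lengths used.
#' @slot rsValues numeric vector of per-scale mean rescaled ranges.
#' @slot nPoints integer, number of samples the fit consumed.
#'
#' @exportClass HurstEstimate
setClass("HurstEstimate",
  representation(
    H = "numeric", logIntercept = "numeric",
    scales = "integer", rsValues = "numeric", nPoints = "integer"
  )
)

setValidity("HurstEstimate", function(object) {
  msgs <- character()
  if (object@H <= 0 || object@H > 1)
    msgs <- c(msgs, "H must lie in (0, 1]")
  if (length(object@scales) &&
      (any(object@scales < 4L) || is.unsorted(object@scales, strictly = TRUE)))
    msgs <- c(msgs, "scales must be strictly increasing and >= 4")
  if (any(object@rsValues <= 0))
    msgs <- c(msgs, "rescaled ranges must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Per-feature calibration result
#'
#' Output of [calibrate()]: for each feature of the input stream, the
#' start-up Hurst exponent and regression intercept fitted on the
#' calibration span, the smoother chosen by the stationarity / trend /
#' random-walk decision rules, the base trailing-window length implied by
#' the continuity grade of the Hurst exponent, and the three diagnostic
#' flags themselves.
#'
#' @slot table data.frame with one row per feature and columns
#'   \code{feature}, \code{h_start}, \code{log_intercept}, \code{smoother},
#'   \code{base_window}, \code{stationary}, \code{trend}, \code{random_walk}.
#' @slot span integer, number of initial samples used.
#' @slot config the [ShadowConfig] the calibration was run under.
#'
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(table = "data.frame", span = "integer", config = "ANY")
)

setValidity("CalibrationResult", function(object) {
  need <- c("feature", "h_start", "log_intercept", "smoother",
            "base_window", "stationary", "trend", "random_walk")
  if (!all(need %in% names(object@table)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

SMOOTHERS <- c("moving_average", "weighted_moving_average",
               "naive_last_value", "detrend_then_moving_average")

#' Shadow-feature generation settings
#'
#' @slot weighting "uniform" (plain trailing mean) or "linear" (weights
#'   w, w-1, ..., 1 from newest to oldest).
#' @slot dynamicWindow logical; re-estimate the window-local Hurst exponent
#'   at every step and let it drive the window length.
#' @slot gradeMapping named numeric of length 5: trailing-window length for
#'   continuity-grade magnitudes 1..5.
#' @slot wMin,wMax integer bounds the window length is clamped to.
#' @slot phiEnabled logical; apply the (|H| - 0.5)/0.5 boost to the newest
#'   sample. When FALSE the boost is held at 0.
#' @slot normalizeDenominator logical; off by default. When TRUE the
#'   denominator absorbs the phi boost so the smoother stays a weighted
#'   mean; the default follows the printed formulas literally.
#' @slot unknownPolicy how warm-up slots are treated at augmentation time:
#'   "mark" (keep the "?" token), "drop" (remove rows), or "backfill"
#'   (copy the first known value backwards).
#' @slot calibrationSpan integer, number of initial samples used by
#'   [calibrate()]; NA means min(1000, ceiling(0.1 N)).
#' @slot alpha numeric significance level shared by the stationarity,
#'   trend, and random-walk tests.
#'
#' @exportClass ShadowConfig
setClass("ShadowConfig",
  representation(
    weighting = "character", dynamicWindow = "logical",
    gradeMapping = "numeric", wMin = "integer", wMax = "integer",
    phiEnabled = "logical", normalizeDenominator = "logical",
    unknownPolicy = "character", calibrationSpan = "integer",
    alpha = "numeric"
  )
)

setValidity("ShadowConfig", function(object) {
  msgs <- character()
  if (!object@weighting %in% c("uniform", "linear"))
    msgs <- c(msgs, "weighting must be 'uniform' or 'linear'")
  if (length(object@gradeMapping) != 5L || any(object@gradeMapping < 2))
    msgs <- c(msgs, "gradeMapping must give 5 window lengths, all >= 2")
  if (is.unsorted(object@gradeMapping))
    msgs <- c(msgs, "gradeMapping must be non-decreasing in grade magnitude")
  if (object@wMin < 2L) msgs <- c(msgs, "wMin must be >= 2")
  if (object@wMax < object@wMin) msgs <- c(msgs, "wMax must be >= wMin")
  if (!object@unknownPolicy %in% c("mark", "drop", "backfill"))
    msgs <- c(msgs, "unknownPolicy must be mark, drop or backfill")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Augmented predictor table
#'
#' Original features side by side with their shadow companions: column
#' \code{j + M} is always the shadow of column \code{j}, named by appending
#' \code{"_shadow"}. Rows removed by the "drop" warm-up policy are recorded.
#'
#' @slot predictors numeric matrix with 2M columns.
#' @slot labels character vector (possibly length 0).
#' @slot policy the unknown-slot policy that was applied.
#' @slot droppedRows integer indices of removed warm-up rows.
#'
#' @exportClass AugmentedDataset
setClass("AugmentedDataset",
  representation(
    predictors = "matrix", labels = "character",
    policy = "character", droppedRows = "integer"
  )
)

setValidity("AugmentedDataset", function(object) {
  msgs <- character()
  if (ncol(object@predictors) %% 2L != 0L)
    msgs <- c(msgs, "predictor count must be 2M (originals then shadows)")
  m <- ncol(object@predictors) / 2L
  cn <- colnames(object@predictors)
  if (!is.null(cn) && m >= 1L &&
      !all(cn[(m + 1L):(2L * m)] == paste0(cn[seq_len(m)], SHADOW_SUFFIX)))
    msgs <- c(msgs, "column j+M must be named <column j>_shadow")
  if (length(object@labels) > 0L &&
      length(object@labels) != nrow(object@predictors))
    msgs <- c(msgs, "labels must match the number of rows")
  if (length(msgs)) msgs else TRUE
})

#' Classifier evaluation report
#'
#' @slot accuracy fraction of correctly classified test instances.
#' @slot kappa Cohen's chance-corrected agreement.
#' @slot macroF unweighted mean per-class F-measure.
#' @slot trainTime seconds spent in model induction (informational).
#' @slot confusion K x K integer matrix, rows = truth, columns = prediction.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    accuracy = "numeric", kappa = "numeric", macroF = "numeric",
    trainTime = "numeric", confusion = "matrix"
  )
)

setValidity("EvalReport", function(object) {
  total <- sum(object@confusion)
  if (total > 0 &&
      abs(object@accuracy - sum(diag(object@confusion)) / total) > 1e-8)
    return("accuracy must equal trace/total of the confusion matrix")
  TRUE
})

#' Streaming shadow generator
#'
#' One-pass, constant-memory-per-feature generator. Holds, per feature, the
#' current window length, a trailing buffer, the latest window-local Hurst
#' exponent and its phi scaling. Reference semantics: pushes mutate the
#' internal environment, so the same object is passed to every
#' [shadowStreamPush()] call.
#'
#' @slot state environment carrying per-feature [WindowState]-style fields.
#'
#' @exportClass ShadowStream
setClass("ShadowStream", representation(state = "environment"))

setMethod("show", "SensorSeries", function(object) {
  cat(sprintf("SensorSeries: %d instances x %d features\n",
              nrow(object@values), ncol(object@values)))
  cat("  features:", paste(colnames(object@values), collapse = ", "), "\n")
  if (length(object@labels))
    cat("  classes:", paste(sort(unique(object@labels)), collapse = ", "),
        "\n")
  if (length(object@samplingRate))
    cat(sprintf("  sampling rate: %g Hz\n", object@samplingRate))
})

setMethod("show", "ShadowSeries", function(object) {
  cat(sprintf("ShadowSeries: %d x %d (%d unknown warm-up slots)\n",
              nrow(object@values), ncol(object@values),
              sum(object@unknownMask)))
})

setMethod("show", "HurstEstimate", function(object) {
  cat(sprintf("HurstEstimate: H = %.4f (log C = %.4f) from %d scales, n = %d\n",
              object@H, object@logIntercept, length(object@scales),
              object@nPoints))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult over %d initial samples:\n", object@span))
  print(object@table, row.names = FALSE)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: accuracy %.4f, kappa %.4f, macro-F %.4f (train %.2fs)\n",
    object@accuracy, object@kappa, object@macroF, object@trainTime))
})
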