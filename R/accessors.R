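#' Construct a SensorSeries
#'
#' @param values numeric matrix or data.frame, N instances by M features.
#' @param timestamps optional numeric vector; defaults to the sample index
#'   0..N-1 so that windows are index-based.
#' @param labels optional character vector of per-row activity classes.
#' @param samplingRate optional sampling rate in Hz. When omitted and the
#'   timestamps look equidistant it is inferred as 1/median(diff).
#' @param featureNames optional feature names; defaults to the column names
#'   of `values` or V1..VM.
#' @return a validated [SensorSeries-class] object.
#' @examples
#' s <- sensorSeries(matrix(rnorm(30), ncol = 3))
#' nSamples(s)
#' @export
sensorSeries <- function(values, timestamps = NULL, labels = NULL,
                         samplingRate = NULL, featureNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(featureNames)) colnames(values) <- featureNames
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (is.null(timestamps)) timestamps <- as.numeric(seq_len(nrow(values)) - 1L)
  if (is.null(samplingRate) && length(timestamps) > 1L) {
    dt <- diff(timestamps)
    md <- stats::median(dt)
    if (md > 0 && all(abs(dt - md) < 1e-6 * max(md, 1)))
      samplingRate <- 1 / md
  }
  new("SensorSeries",
      values = values,
      timestamps = as.numeric(timestamps),
      labels = if (is.null(labels)) character() else as.character(labels),
      samplingRate = if (is.null(samplingRate)) numeric()
                     else as.numeric(samplingRate))
}

#' @rdname sensorSeries
#' @param x a SensorSeries or ShadowSeries.
#' @export
sensorValues <- function(x) x@values

#' @rdname sensorSeries
#' @export
timestamps <- function(x) x@timestamps

#' @rdname sensorSeries
#' @export
activityLabels <- function(x) x@labels

#' @rdname sensorSeries
#' @export
samplingRate <- function(x)
  if (length(x@samplingRate)) x@samplingRate else NA_real_

#' @rdname sensorSeries
#' @export
nSamples <- function(x) nrow(x@values)

#' @rdname sensorSeries
#' @export
nFeatures <- function(x) ncol(x@values)

#' @rdname sensorSeries
#' @export
featureNames <- function(x) colnames(x@values)

#' Accessors for ShadowSeries
#'
#' @param x a [ShadowSeries-class].
#' @return `shadowValues` the numeric matrix (NA on warm-up slots),
#'   `unknownMask` the logical warm-up mask.
#' @export
shadowValues <- function(x) {
  v <- x@values
  v[x@unknownMask] <- NA_real_
  v
}

#' @rdname shadowValues
#' @export
unknownMask <- function(x) x@unknownMask

#' Accessors for HurstEstimate
#' @param x a [HurstEstimate-class].
#' @export
hurstExponent <- function(x) x@H

#' @rdname hurstExponent
#' @export
logIntercept <- function(x) x@logIntercept

#' @rdname hurstExponent
#' @export
hurstScales <- function(x) x@scales

#' @rdname hurstExponent
#' @export
rsValues <- function(x) x@rsValues

#' Accessors for CalibrationResult
#' @param x a [CalibrationResult-class].
#' @return `calibrationTable` the per-feature data.frame;
#'   `calibrationSpan` the number of initial samples used.
#' @export
calibrationTable <- function(x) x@table

#' @rdname calibrationTable
#' @export
calibrationSpan <- function(x) x@span

#' Accessors for AugmentedDataset
#' @param x an [AugmentedDataset-class].
#' @export
predictors <- function(x) x@predictors

#' @rdname predictors
#' @export
droppedRows <- function(x) x@droppedRows

#' Accessors for EvalReport
#' @param x an [EvalReport-class].
#' @export
confusionMatrix <- function(x) x@confusion

#' Shadow generation settings
#'
#' Builds a validated [ShadowConfig-class]. Defaults: uniform weighting,
#' dynamic windows on, phi boost on, grade-to-window mapping
#' `c(8, 16, 32, 64, 128)` samples for continuity-grade magnitudes 1..5,
#' window bounds [2, 512], warm-up slots marked "?", calibration span
#' `min(1000, ceiling(0.1 N))`, and a 0.05 significance level for the
#' characterization tests.
#'
#' @param weighting "uniform" or "linear".
#' @param dynamicWindow logical, adapt the window length on the fly.
#' @param gradeMapping numeric length 5, window length per grade magnitude.
#' @param wMin,wMax window-length clamp.
#' @param phiEnabled logical, apply the Hurst-derived boost to the newest
#'   sample.
#' @param normalizeDenominator logical; when TRUE the phi boost is folded
#'   into the denominator so the output stays a weighted mean. Off by
#'   default: the printed formulas inflate only the numerator.
#' @param unknownPolicy "mark", "drop" or "backfill".
#' @param calibrationSpan integer or NA (auto).
#' @param alpha significance level for the calibration tests.
#' @return a [ShadowConfig-class] object.
#' @examples
#' cfg <- shadowConfig(weighting = "linear", dynamicWindow = FALSE)
#' @export
shadowConfig <- function(weighting = c("uniform", "linear"),
                         dynamicWindow = TRUE,
                         gradeMapping = c(8, 16, 32, 64, 128),
                         wMin = 2L, wMax = 512L,
                         phiEnabled = TRUE,
                         normalizeDenominator = FALSE,
                         unknownPolicy = c("mark", "drop", "backfill"),
                         calibrationSpan = NA_integer_,
                         alpha = 0.05) {
  new("ShadowConfig",
      weighting = match.arg(weighting),
      dynamicWindow = dynamicWindow,
      gradeMapping = as.numeric(gradeMapping),
      wMin = as.integer(wMin), wMax = as.integer(wMax),
      phiEnabled = phiEnabled,
      normalizeDenominator = normalizeDenominator,
      unknownPolicy = match.arg(unknownPolicy),
      calibrationSpan = as.integer(calibrationSpan),
      alpha = alpha)
}
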