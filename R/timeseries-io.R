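# CSV reading/writing for sensor streams. Dialect: comma-separated, UTF-8,
# one header row; unknown slots are the literal token "?" on output, and
# "?" or an empty cell maps to unknown on input.

#' Read a sensor CSV into a SensorSeries
#'
#' @param path file path.
#' @param timestampColumn name of the timestamp column, or `"index"` when
#'   rows are index-timed (no timestamp column in the file).
#' @param featureColumns character vector of feature column names; default
#'   NULL takes every column that is neither timestamp nor label, in file
#'   order.
#' @param labelColumn name of the class-label column, `NULL` for none. The
#'   default `"auto"` uses the last column if it is non-numeric, matching
#'   the (features | class) layout with the class last.
#' @return a validated [SensorSeries-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSensorCSV(sensorSeries(matrix(1:6 / 2, ncol = 2)), f)
#' readSensorCSV(f)
#' @export
readSensorCSV <- function(path, timestampColumn = "index",
                          featureColumns = NULL, labelColumn = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("?", ""),
                        colClasses = NA, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty CSV: ", path)
  cols <- names(df)
  if (identical(labelColumn, "auto")) {
    last <- df[[length(cols)]]
    labelColumn <- if (!is.numeric(last) &&
                       !identical(cols[length(cols)], timestampColumn))
      cols[length(cols)] else NULL
  }
  if (!is.null(labelColumn) && !labelColumn %in% cols)
    stop("schema error: label column '", labelColumn, "' not in file")
  ts <- NULL
  if (!identical(timestampColumn, "index")) {
    if (!timestampColumn %in% cols)
      stop("schema error: timestamp column '", timestampColumn,
           "' not in file")
    ts <- as.numeric(df[[timestampColumn]])
    if (anyDuplicated(ts))
      stop("validation error: duplicated timestamp at row ",
           anyDuplicated(ts))
  }
  if (is.null(featureColumns))
    featureColumns <- setdiff(cols, c(timestampColumn, labelColumn))
  missing_cols <- setdiff(featureColumns, cols)
  if (length(missing_cols))
    stop("schema error: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  feat <- df[featureColumns]
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf(
          "parse error: non-numeric value '%s' in column '%s' at data row %d",
          col[bad[1L]], featureColumns[j], bad[1L]))
      feat[[j]] <- num
    }
  }
  sensorSeries(as.matrix(feat), timestamps = ts,
               labels = if (is.null(labelColumn)) NULL
                        else as.character(df[[labelColumn]]))
}

#' Write a SensorSeries (or augmented table) to CSV
#'
#' Serializes one header row then N data rows. Unknown slots (NA values, or
#' masked slots of a [ShadowSeries-class] column set) become the literal
#' token `"?"`. When the series carries labels they are written as a final
#' `class` column; an unlabeled series gets no label column.
#'
#' @param x a [SensorSeries-class], an [AugmentedDataset-class], or a plain
#'   data.frame/matrix.
#' @param path output file path.
#' @param timestampColumn name for the timestamp column; `NULL` omits it
#'   (index-timed data round-trips via `timestampColumn = "index"`).
#' @return invisibly, the path.
#' @export
writeSensorCSV <- function(x, path, timestampColumn = NULL) {
  if (is(x, "SensorSeries")) {
    df <- as.data.frame(x@values)
    if (!is.null(timestampColumn)) {
      df <- cbind(stats::setNames(data.frame(x@timestamps), timestampColumn),
                  df)
    }
    if (length(x@labels)) df$class <- x@labels
  } else if (is(x, "AugmentedDataset")) {
    df <- as.data.frame(x@predictors)
    if (length(x@labels)) df$class <- x@labels
  } else {
    df <- as.data.frame(x)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "?", quote = FALSE)
  invisible(path)
}

#' Read an augmented predictor CSV
#'
#' Counterpart of [writeSensorCSV()] for tables written from an
#' [AugmentedDataset-class]: columns are M originals, their M `_shadow`
#' companions, and optionally a final `class` column. `"?"` (or empty)
#' cells map back to NA, so a "mark"-policy table round-trips.
#'
#' @param path file path.
#' @return an [AugmentedDataset-class] with policy `"mark"`.
#' @export
readAugmentedCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("?", ""),
                        stringsAsFactors = FALSE)
  labs <- character()
  if ("class" %in% names(df)) {
    labs <- as.character(df$class)
    df$class <- NULL
  }
  pred <- as.matrix(df)
  storage.mode(pred) <- "double"
  new("AugmentedDataset", predictors = pred, labels = labs,
      policy = "mark", droppedRows = integer())
}

#' Validate a sensor series (report-only)
#'
#' Never mutates or rejects: returns a report listing monotonicity
#' violations of the timestamp vector, NaN/NA counts per feature, and the
#' inferred sampling rate (reciprocal of the median timestamp step) with
#' the fraction of steps deviating from the median by more than 1%.
#'
#' @param series a [SensorSeries-class].
#' @return a list with elements `monotonic` (logical),
#'   `monotonicityViolations` (row indices where the timestamp does not
#'   increase), `nanCounts` (named integer per feature), `inferredRate`
#'   (Hz) and `jitterFraction`.
#' @examples
#' validateSeries(sensorSeries(matrix(rnorm(20), ncol = 2)))
#' @export
validateSeries <- function(series) {
  ts <- series@timestamps
  dt <- diff(ts)
  viol <- which(dt <= 0) + 1L
  md <- stats::median(dt)
  rate <- if (length(dt) && md > 0) 1 / md else NA_real_
  jitter <- if (length(dt) && md > 0) mean(abs(dt - md) > 0.01 * md)
            else NA_real_
  bad <- apply(series@values, 2L, function(col) sum(!is.finite(col)))
  list(monotonic = length(viol) == 0L,
       monotonicityViolations = viol,
       nanCounts = bad,
       inferredRate = rate,
       jitterFraction = jitter)
}
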