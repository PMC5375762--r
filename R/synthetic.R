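# Seeded generators: fractional Gaussian noise with exact target Hurst
# exponent (circulant embedding), and labeled synthetic activity streams
# emulating wearable-accelerometer and skeletal motion-capture data.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate fractional Gaussian noise
#'
#' Exact synthesis by circulant embedding (Davies-Harte): the fGn
#' autocovariance \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2}
#' is embedded in a circulant matrix whose eigenvalues are obtained by FFT,
#' and one draw of the resulting stationary Gaussian process has exactly the
#' target covariance. Used as the known-H oracle when validating the R/S
#' estimator. For n not a power of two, a longer power-of-two sample is
#' generated and truncated (truncation of an exact sample stays exact).
#'
#' The generator is a pure function of (H, n, seed): the global RNG state is
#' saved and restored.
#'
#' @param H target Hurst exponent, in (0, 1).
#' @param n number of samples, >= 64.
#' @param seed integer seed.
#' @return numeric vector of length n with unit marginal variance.
#' @examples
#' x <- simulateFGN(0.9, 1024, seed = 7)
#' @export
simulateFGN <- function(H, n, seed) {
  if (!is.finite(H) || H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  if (n < 64L) stop("n must be at least 64")
  n2 <- 2^ceiling(log2(n))
  m <- 2L * n2
  k <- 0:n2
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(gamma, rev(gamma[2:n2]))
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0  # tiny negative rounding noise
  with_seed(seed, {
    a <- stats::rnorm(n2 + 1L)
    b <- stats::rnorm(n2 - 1L)
    w <- complex(length.out = m)
    w[1L] <- sqrt(lambda[1L] / m) * a[1L]
    w[n2 + 1L] <- sqrt(lambda[n2 + 1L] / m) * a[n2 + 1L]
    idx <- 2:n2
    w[idx] <- sqrt(lambda[idx] / (2 * m)) * (a[idx] + 1i * b[idx - 1L])
    w[m + 2L - idx] <- Conj(w[idx])
    Re(stats::fft(w))[seq_len(n)]
  })
}

#' Activity-stream generator settings
#'
#' Describes a synthetic multi-activity motion stream: one quasi-periodic
#' bout per activity, each feature being
#' baseline + amplitude * sin(2 pi f t + phase) + Gaussian noise, sampled at
#' a constant rate. Random phases (per bout and axis) and the noise are the
#' only stochastic elements; the stream is a pure function of (spec, seed).
#'
#' @slot activities data.frame with columns `label`, `amplitude`,
#'   `frequency` (Hz), `noise_sd`.
#' @slot baselines numeric matrix, one row per activity, one column per
#'   feature: the per-activity posture level of each channel.
#' @slot samplingRate sampling rate in Hz.
#' @slot segmentLength samples per activity bout.
#' @slot seed integer seed.
#'
#' @exportClass ActivitySpec
setClass("ActivitySpec",
  representation(
    activities = "data.frame", baselines = "matrix",
    samplingRate = "numeric", segmentLength = "integer", seed = "integer"
  )
)

setValidity("ActivitySpec", function(object) {
  a <- object@activities
  msgs <- character()
  need <- c("label", "amplitude", "frequency", "noise_sd")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("activities needs columns:",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(a$label)) msgs <- c(msgs, "labels must be unique")
    if (any(a$noise_sd < 0)) msgs <- c(msgs, "noise_sd must be >= 0")
    if (any(a$frequency >= object@samplingRate / 2))
      msgs <- c(msgs, "frequencies must be below the Nyquist rate")
  }
  if (nrow(object@baselines) != nrow(a))
    msgs <- c(msgs, "baselines must have one row per activity")
  if (object@segmentLength < 1L) msgs <- c(msgs, "segmentLength must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ActivitySpec-class
#' @param activities data.frame (label, amplitude, frequency, noise_sd).
#' @param baselines matrix of per-activity, per-feature posture levels.
#' @param samplingRate Hz, default 50.
#' @param segmentLength samples per bout, default 2000.
#' @param seed integer.
#' @export
activitySpec <- function(activities, baselines, samplingRate = 50,
                         segmentLength = 2000L, seed = 1L) {
  new("ActivitySpec",
      activities = as.data.frame(activities),
      baselines = as.matrix(baselines),
      samplingRate = as.numeric(samplingRate),
      segmentLength = as.integer(segmentLength),
      seed = as.integer(seed))
}

#' Default tri-axial accelerometer spec
#'
#' Seven activities at 50 Hz on three axes. Fluctuation (per-bout variance)
#' is ordered sit, stand (least) < null < walk < stairup, stairdown < bike
#' (most). Classes overlap in level but differ in dynamics: sit/stand share
#' a posture baseline and amplitude and differ only in oscillation
#' frequency, as do stairup/stairdown — instantaneous readings cannot tell
#' them apart, while trailing means (whose frequency attenuation depends on
#' the window) can.
#'
#' @param segmentLength samples per activity bout (default 2000, giving the
#'   14000 x 3 default stream).
#' @param seed integer.
#' @return an [ActivitySpec-class].
#' @export
defaultActivitySpec <- function(segmentLength = 2000L, seed = 1L) {
  acts <- data.frame(
    label     = c("sit", "stand", "null", "walk", "stairup", "stairdown",
                  "bike"),
    amplitude = c(0.05, 0.05, 0.12, 0.80, 1.10, 1.10, 1.50),
    frequency = c(0.30, 2.50, 0.20, 1.80, 0.70, 2.80, 1.20),
    noise_sd  = c(0.03, 0.03, 0.06, 0.15, 0.20, 0.20, 0.25)
  )
  base <- rbind(
    sit       = c(0.1, 9.7, 0.2),
    stand     = c(0.1, 9.7, 0.2),
    null      = c(0.0, 2.0, 9.5),
    walk      = c(0.3, 9.5, 1.0),
    stairup   = c(0.3, 9.5, 1.0),
    stairdown = c(0.3, 9.5, 1.0),
    bike      = c(0.5, 8.0, 3.0)
  )
  colnames(base) <- c("x", "y", "z")
  activitySpec(acts, base, samplingRate = 50,
               segmentLength = segmentLength, seed = seed)
}

#' Default skeletal (wide) spec: 64 features, 30 activities
#'
#' Emulates skeletal motion-capture streams: 64 channels organised as
#' 3-channel joints sharing a per-activity posture baseline, 30 activity
#' classes whose amplitude, frequency and noise sweep a realistic range.
#' Joint baselines are drawn once, deterministically from the seed.
#'
#' @param segmentLength samples per activity bout (default 200).
#' @param seed integer.
#' @return an [ActivitySpec-class] with 64 baseline columns.
#' @export
defaultSkeletonSpec <- function(segmentLength = 200L, seed = 1L) {
  nAct <- 30L
  nFeat <- 64L
  k <- seq_len(nAct) - 1L
  acts <- data.frame(
    label     = sprintf("act%02d", seq_len(nAct)),
    amplitude = 0.05 + 1.45 * k / (nAct - 1L),
    frequency = rep(c(0.3, 0.8, 1.5, 2.4, 3.2), length.out = nAct),
    noise_sd  = 0.02 + 0.20 * k / (nAct - 1L)
  )
  base <- with_seed(seed + 104729L, {
    joint <- matrix(stats::rnorm(nAct * ceiling(nFeat / 3)), nrow = nAct)
    b <- joint[, rep(seq_len(ncol(joint)), each = 3L)[seq_len(nFeat)]]
    b + matrix(stats::rnorm(nAct * nFeat, sd = 0.1), nrow = nAct)
  })
  colnames(base) <- sprintf("j%02d_%s", (seq_len(nFeat) - 1L) %/% 3L + 1L,
                            c("x", "y", "z")[(seq_len(nFeat) - 1L) %% 3L + 1L])
  activitySpec(acts, base, samplingRate = 30,
               segmentLength = segmentLength, seed = seed)
}

#' Simulate a labeled activity stream
#'
#' Concatenates one bout per activity in spec order. Each feature of a bout
#' is baseline + amplitude * sin(2 pi f t + phase) + N(0, noise_sd^2), with
#' an independent uniform phase per (bout, feature). Deterministic given
#' the spec's seed; a different seed changes values but not the label
#' sequence.
#'
#' @param spec an [ActivitySpec-class].
#' @return a labeled [SensorSeries-class] with
#'   N = nrow(activities) * segmentLength rows.
#' @examples
#' s <- simulateActivityStream(defaultActivitySpec(segmentLength = 100L))
#' table(activityLabels(s))
#' @export
simulateActivityStream <- function(spec) {
  validObject(spec)
  a <- spec@activities
  nAct <- nrow(a)
  m <- ncol(spec@baselines)
  len <- spec@segmentLength
  fs <- spec@samplingRate
  tt <- (seq_len(len) - 1L) / fs
  vals <- with_seed(spec@seed, {
    out <- vector("list", nAct)
    for (i in seq_len(nAct)) {
      phases <- stats::runif(m, 0, 2 * pi)
      sig <- vapply(seq_len(m), function(j) {
        spec@baselines[i, j] +
          a$amplitude[i] * sin(2 * pi * a$frequency[i] * tt + phases[j]) +
          stats::rnorm(len, sd = a$noise_sd[i])
      }, numeric(len))
      out[[i]] <- sig
    }
    do.call(rbind, out)
  })
  colnames(vals) <- colnames(spec@baselines)
  n <- nrow(vals)
  sensorSeries(vals,
               timestamps = (seq_len(n) - 1L) / fs,
               labels = rep(a$label, each = len),
               samplingRate = fs)
}

#' Simulate a skeletal-like wide stream
#'
#' Convenience wrapper: simulates from a 64-feature, 30-activity spec (see
#' [defaultSkeletonSpec()]).
#'
#' @param spec an [ActivitySpec-class]; defaults to [defaultSkeletonSpec()].
#' @return a labeled [SensorSeries-class] with 64 features and 30 classes.
#' @export
simulateSkeletonStream <- function(spec = defaultSkeletonSpec()) {
  simulateActivityStream(spec)
}
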