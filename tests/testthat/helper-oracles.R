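# Independent brute-force oracles used across the suite.

# Trailing moving average: plain loop, no shared code with the package.
oracle_trailing_mean <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= w) out[i] <- mean(x[(i - w + 1):i])
  }
  out
}

# A tiny labeled series for IO tests.
tiny_series <- function(n = 5L, m = 3L, labeled = TRUE) {
  sensorSeries(matrix(seq_len(n * m) / 2, nrow = n,
                      dimnames = list(NULL, paste0("f", seq_len(m)))),
               labels = if (labeled) rep(c("a", "b"), length.out = n))
}

static_config <- function(weighting = "uniform")
  shadowConfig(weighting = weighting, dynamicWindow = FALSE,
               phiEnabled = FALSE)
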