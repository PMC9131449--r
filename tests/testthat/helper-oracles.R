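# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation they check.

oracleMean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracleCentralMoment <- function(x, k) {
  m <- oracleMean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^k
  s / length(x)
}

oracleSkewness <- function(x) {
  n <- length(x)
  g1 <- oracleCentralMoment(x, 3) / oracleCentralMoment(x, 2)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

oracleExcessKurtosis <- function(x) {
  n <- length(x)
  g2 <- oracleCentralMoment(x, 4) / oracleCentralMoment(x, 2)^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# Interval-by-interval trapezoid, accumulated in a loop.
oracleTrapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# Frame-by-frame difference-of-means over three matched matrices.
oracleEsmacs <- function(com, pro, lig) {
  tot <- 0
  cnt <- 0
  for (r in seq_len(ncol(com))) for (f in seq_len(nrow(com))) {
    tot <- tot + (com[f, r] - pro[f, r] - lig[f, r])
    cnt <- cnt + 1L
  }
  tot / cnt
}

# Counting loop for the six half-open sigma bins about the mean.
oracleBins <- function(values) {
  m <- oracleMean(values)
  s <- sqrt(oracleCentralMoment(values, 2) * length(values) /
              (length(values) - 1L))
  counts <- numeric(6L)
  for (v in values) {
    z <- (v - m) / s
    b <- if (z < -2) 1L else if (z < -1) 2L else if (z < 0) 3L else
         if (z < 1) 4L else if (z < 2) 5L else 6L
    counts[b] <- counts[b] + 1L
  }
  100 * counts / length(values)
}

oracleErrorMetrics <- function(expVals, calcVals) {
  su <- 0; ss <- 0
  for (i in seq_along(expVals)) {
    d <- calcVals[i] - expVals[i]
    su <- su + abs(d)
    ss <- ss + d
  }
  list(mue = su / length(expVals), mse = ss / length(expVals))
}
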