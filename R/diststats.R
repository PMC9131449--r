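# Distribution-characterization stage for repeated assay measurements:
# bias-corrected moments, sigma-bin occupancy against the analytic normal
# reference, tail probabilities, histogram/KDE summaries and a
# permutation-based drift diagnostic.

#' Adjusted sample skewness and excess kurtosis
#'
#' `sampleSkewness` is the adjusted Fisher-Pearson standardized third
#' moment, `g1 * sqrt(n (n-1)) / (n - 2)`; `sampleExcessKurtosis` is the
#' bias-corrected fourth standardized moment minus 3,
#' `((n+1) g2 + 6) (n-1) / ((n-2)(n-3))`.  These are the common defaults
#' for samples of a few hundred measurements; the estimator choice is
#' isolated here so it can be swapped in one place.
#'
#' @param x Numeric vector; `n >= 3` (skewness) or `n >= 4` (kurtosis),
#'   with nonzero variance.
#' @return The estimate (dimensionless).
#' @export
sampleSkewness <- function(x) {
  x <- assertFinite(x, "x")
  n <- length(x)
  if (n < 3L) stop("skewness needs n >= 3")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("skewness undefined for zero-variance data")
  g1 <- mean((x - mean(x))^3) / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @rdname sampleSkewness
#' @export
sampleExcessKurtosis <- function(x) {
  x <- assertFinite(x, "x")
  n <- length(x)
  if (n < 4L) stop("excess kurtosis needs n >= 4")
  v <- mean((x - mean(x))^2)
  if (v == 0) stop("kurtosis undefined for zero-variance data")
  g2 <- mean((x - mean(x))^4) / v^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Occupancy of one-sigma bins about the mean
#'
#' Fraction of values (as percentages) in the six half-open bins
#' `(-Inf, -2s)`, `[-2s, -s)`, `[-s, 0)`, `[0, s)`, `[s, 2s)`, `[2s, Inf)`
#' about the sample mean, where `s` is the SD of the best-fit normal --
#' i.e. the maximum-likelihood fit, which is the sample mean and (n-1)
#' denominator) sample SD.  Compare against [normalReferenceBins()] to see
#' asymmetry and tail weight at a glance.
#'
#' @param values Numeric vector, `n >= 2`, nonzero SD.
#' @return Numeric vector of six percentages summing to 100.
#' @export
sigmaBinFractions <- function(values) {
  values <- assertFinite(values, "values")
  if (length(values) < 2L) stop("need n >= 2")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) stop("sigma bins undefined for zero-variance data")
  edges <- m + c(-Inf, -2, -1, 0, 1, 2, Inf) * s
  counts <- vapply(seq_len(6L), function(i)
    sum(values >= edges[i] & values < edges[i + 1L]), numeric(1L))
  100 * counts / length(values)
}

#' Analytic normal occupancy of the one-sigma bins
#'
#' Standard-normal probabilities (as percentages) of the six bins used by
#' [sigmaBinFractions()]: (2.275, 13.591, 34.134, 34.134, 13.591, 2.275),
#' i.e. (2.3, 13.6, 34.1, 34.1, 13.6, 2.3) to one decimal.
#'
#' @return Numeric vector of six percentages summing to 100.
#' @export
normalReferenceBins <- function() {
  p <- stats::pnorm(c(-2, -1, 0, 1, 2))
  100 * diff(c(0, p, 1))
}

#' Empirical tail probability with its normal reference
#'
#' Fraction of values beyond `kSigma` standard deviations from the mean on
#' the requested side, paired with the probability a normal distribution
#' would put there.  A heavy left tail shows up as an empirical value well
#' above the reference (e.g. 5.2% beyond 2 sigma on the left versus the
#' normal 2.3%).
#'
#' @param values Numeric vector with nonzero SD.
#' @param kSigma Positive number of standard deviations.
#' @param side `"left"`, `"right"` or `"both"`.
#' @return List with `empirical` and `normalReference` (percentages).
#' @export
tailProbability <- function(values, kSigma = 2,
                            side = c("left", "right", "both")) {
  side <- match.arg(side)
  values <- assertFinite(values, "values")
  if (!is.numeric(kSigma) || length(kSigma) != 1L || kSigma <= 0)
    stop("'kSigma' must be a single positive number")
  m <- mean(values)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("tail probability undefined for zero-variance data")
  emp <- switch(side,
    left = mean(values < m - kSigma * s),
    right = mean(values > m + kSigma * s),
    both = mean(abs(values - m) > kSigma * s))
  ref <- switch(side,
    left = stats::pnorm(-kSigma),
    right = stats::pnorm(-kSigma),
    both = 2 * stats::pnorm(-kSigma))
  list(empirical = 100 * emp, normalReference = 100 * ref)
}

# ---------------------------------------------------------------------------
# DistributionSummary
# ---------------------------------------------------------------------------

#' DistributionSummary: descriptive statistics of an assay distribution
#'
#' @slot n Number of measurements.
#' @slot mean,sd Sample mean and (n-1) SD, pIC50 units.
#' @slot skewness,excessKurtosis Adjusted sample moments.
#' @slot binFractions Six sigma-bin percentages (see
#'   [sigmaBinFractions()]).
#' @slot leftTail2Sigma Percentage of values more than 2 SD below the mean.
#' @exportClass DistributionSummary
setClass("DistributionSummary",
  slots = c(n = "integer", mean = "numeric", sd = "numeric",
            skewness = "numeric", excessKurtosis = "numeric",
            binFractions = "numeric", leftTail2Sigma = "numeric"))

setValidity("DistributionSummary", function(object) {
  msg <- character()
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (length(object@binFractions) != 6L ||
      abs(sum(object@binFractions) - 100) > 1e-6)
    msg <- c(msg, "binFractions must be six percentages summing to 100")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistributionSummary", function(object) {
  cat(sprintf("DistributionSummary: n = %d\n", object@n))
  cat(sprintf("  mean %.2f  SD %.2f  skewness %.2f  excess kurtosis %.2f\n",
              object@mean, object@sd, object@skewness,
              object@excessKurtosis))
  bins <- c("(-Inf,-2s)", "[-2s,-s)", "[-s,0)", "[0,s)", "[s,2s)", "[2s,Inf)")
  cat("  sigma bins (%):\n")
  cat("   ", paste(sprintf("%s %.1f", bins, object@binFractions),
                   collapse = "  "), "\n")
  ref <- normalReferenceBins()
  cat("    normal ref ", paste(sprintf("%.1f", ref), collapse = "  "), "\n")
})

#' Summarize the distribution of repeated measurements
#'
#' Mean, SD, adjusted skewness and excess kurtosis, sigma-bin occupancy
#' and the left 2-sigma tail fraction of a vector of repeated assay
#' measurements (or an [AssayReplicates-class] object).
#'
#' @param values Numeric vector (`n >= 4`, nonzero SD) or an
#'   `AssayReplicates` object.
#' @return A [DistributionSummary-class].
#' @examples
#' a <- simulateAssayReplicates(500, mean = 7.47, sd = 0.19,
#'                              skewness = 2.04, excessKurtosis = 7.56)
#' summarizeDistribution(a)
#' @export
summarizeDistribution <- function(values) {
  if (is(values, "AssayReplicates")) values <- assayValues(values)
  values <- assertFinite(values, "values")
  n <- length(values)
  if (n < 4L) stop("moments beyond the SD need n >= 4")
  if (stats::sd(values) == 0)
    stop("skewness/kurtosis undefined for zero-variance data")
  new("DistributionSummary",
      n = n, mean = mean(values), sd = stats::sd(values),
      skewness = sampleSkewness(values),
      excessKurtosis = sampleExcessKurtosis(values),
      binFractions = sigmaBinFractions(values),
      leftTail2Sigma = tailProbability(values, 2, "left")$empirical)
}

#' Histogram and kernel density summary of assay measurements
#'
#' Fixed-width histogram (default bin size 0.05 pIC50 units) with bin
#' edges aligned to multiples of the bin size, plus a Gaussian kernel
#' density estimate with Silverman's rule-of-thumb bandwidth, and the
#' sample mean for marking on plots.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param binSize Histogram bin width (> 0; default 0.05).
#' @return Object of class `kdeHistogram`: list with `breaks`, `counts`,
#'   `mids`, `density` (data frame `x`, `y`), `mean`, `binSize`.
#' @export
kdeHistogram <- function(values, binSize = 0.05) {
  values <- assertFinite(values, "values")
  if (length(values) < 2L) stop("need n >= 2")
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize <= 0)
    stop("'binSize' must be a single positive number")
  lo <- floor(min(values) / binSize) * binSize
  hi <- ceiling(max(values) / binSize) * binSize
  if (hi <= lo) hi <- lo + binSize
  breaks <- seq(lo, hi + binSize / 2, by = binSize)
  counts <- vapply(seq_len(length(breaks) - 1L), function(i)
    sum(values >= breaks[i] & values < breaks[i + 1L]), numeric(1L))
  # values exactly at the last break belong to the last bin
  counts[length(counts)] <- counts[length(counts)] +
    sum(values == breaks[length(breaks)])
  dens <- if (stats::sd(values) > 0)
    stats::density(values, bw = "nrd0") else NULL
  structure(list(
    breaks = breaks, counts = counts,
    mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
    density = if (is.null(dens)) NULL else data.frame(x = dens$x, y = dens$y),
    mean = mean(values), binSize = binSize), class = "kdeHistogram")
}

#' @export
plot.kdeHistogram <- function(x, main = "", xlab = "pIC50", ...) {
  h <- graphics::barplot(x$counts / sum(x$counts) / x$binSize,
                         width = x$binSize, space = 0,
                         col = "grey85", border = "grey60",
                         main = main, xlab = xlab, ylab = "density", ...)
  if (!is.null(x$density))
    graphics::lines((x$density$x - x$breaks[1L]), x$density$y, lwd = 2)
  graphics::abline(v = x$mean - x$breaks[1L], lty = 2)
  invisible(x)
}

#' Permutation test for assay drift over time
#'
#' Least-squares slope of the measurements on their measurement index (or
#' supplied ordering), with a two-sided permutation p-value: the slope is
#' recomputed under random shuffles of the values and compared in absolute
#' value.  A permutation test is used instead of the parametric t-test
#' because these measurement distributions are themselves non-normal.
#'
#' @param values Numeric vector, `n >= 10`.
#' @param index Measurement order (default `seq_along(values)`); must be
#'   non-constant.
#' @param nPerm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param alpha Flag threshold (default 0.05).
#' @return List with `slope` (units per index), `se` (OLS standard error,
#'   for scale), `p` (permutation p-value) and `driftFlag` (`p < alpha`).
#' @export
driftTest <- function(values, index = seq_along(values), nPerm = 10000,
                      seed = 42, alpha = 0.05) {
  values <- assertFinite(values, "values")
  n <- length(values)
  if (n < 10L) stop("drift test needs n >= 10")
  index <- assertFinite(index, "index")
  if (length(index) != n) stop("'index' must match 'values' in length")
  if (stats::var(index) == 0) stop("'index' must not be constant")
  nPerm <- assertCount(nPerm, "nPerm")
  ic <- index - mean(index)
  ssx <- sum(ic^2)
  slope <- sum(ic * values) / ssx
  resid <- (values - mean(values)) - slope * ic
  se <- sqrt(sum(resid^2) / (n - 2) / ssx)
  if (stats::var(values) == 0) {
    return(list(slope = 0, se = 0, p = 1, driftFlag = FALSE))
  }
  permAbs <- withSeed(seed, vapply(seq_len(nPerm), function(b)
    abs(sum(ic * values[sample.int(n)]) / ssx), numeric(1L)))
  p <- (1 + sum(permAbs >= abs(slope))) / (nPerm + 1)
  list(slope = slope, se = se, p = p, driftFlag = p < alpha)
}
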