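#' @importFrom stats rnorm sd var cor cor.test density pnorm qnorm lm coef
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
#' @importFrom graphics barplot lines abline
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic functions in the package route through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

assertNonNegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name))
  as.numeric(x)
}

assertFinite <- function(x, name) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop(sprintf("'%s' must be finite and numeric", name))
  as.numeric(x)
}

# Trapezoidal quadrature on sorted nodes; the TI estimator's quadrature rule.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapezoid needs at least two nodes")
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}
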