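# Comparison stage: potency-to-free-energy conversion, agreement
# statistics between calculated and experimental values, cross-platform
# reproducibility, and systematic per-compound offsets.

# Gas constant in kcal/(mol K).
R_KCAL <- 1.9872e-3

#' Convert pIC50 to a binding free energy
#'
#' `dG = R T ln(IC50) = -R T ln(10) pIC50` with `R = 1.9872e-3`
#' kcal/(mol K); pIC50 is `-log10` of the molar IC50.  At the default
#' T = 300 K one pIC50 unit corresponds to -1.3727 kcal/mol.
#'
#' @param pIC50 Potency values (vectorized).
#' @param temperatureK Absolute temperature in kelvin (default 300).
#' @return Free energies in kcal/mol.
#' @examples
#' pic50ToDg(6)  # -8.236 kcal/mol
#' @export
pic50ToDg <- function(pIC50, temperatureK = 300) {
  pIC50 <- assertFinite(pIC50, "pIC50")
  if (!is.finite(temperatureK) || temperatureK <= 0)
    stop("'temperatureK' must be positive")
  -R_KCAL * temperatureK * log(10) * pIC50
}

#' @rdname pic50ToDg
#' @param dg Free energies in kcal/mol.
#' @export
dgToPic50 <- function(dg, temperatureK = 300) {
  dg <- assertFinite(dg, "dg")
  if (!is.finite(temperatureK) || temperatureK <= 0)
    stop("'temperatureK' must be positive")
  -dg / (R_KCAL * temperatureK * log(10))
}

#' Correlation coefficient with a 95% confidence interval
#'
#' Pearson or Spearman correlation with a percentile-bootstrap confidence
#' interval over paired resampling (the default: it makes no normality
#' assumption, in keeping with the observation that free-energy data are
#' generally not normal).  A Fisher-z interval is available behind
#' `ciMethod = "fisher"`.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param method `"pearson"` or `"spearman"`.
#' @param nBoot Bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param ciMethod `"bootstrap"` (percentile) or `"fisher"`.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci` (length-2), `method`, `ciMethod`, `n`.
#' @export
correlationWithCI <- function(x, y, method = c("pearson", "spearman"),
                              nBoot = 10000, seed = 42,
                              ciMethod = c("bootstrap", "fisher"),
                              conf = 0.95) {
  method <- match.arg(method)
  ciMethod <- match.arg(ciMethod)
  x <- assertFinite(x, "x"); y <- assertFinite(y, "y")
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 4L) stop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant input vector")
  est <- stats::cor(x, y, method = method)
  alpha <- (1 - conf) / 2
  ci <- if (ciMethod == "fisher") {
    z <- atanh(est)
    # classical variance for Pearson; Fieller-style inflation for Spearman
    sz <- if (method == "pearson") 1 / sqrt(n - 3) else 1.06 / sqrt(n - 3)
    tanh(z + stats::qnorm(c(alpha, 1 - alpha)) * sz)
  } else {
    nBoot <- assertCount(nBoot, "nBoot")
    boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i], method = method)
    }, numeric(1L)))
    unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(estimate = est, ci = ci, method = method, ciMethod = ciMethod, n = n)
}

#' Mean unsigned and signed error between calculation and experiment
#'
#' @param expVals,calcVals Paired numeric vectors (kcal/mol).
#' @return List with `mue = mean(|calc - exp|)` and
#'   `mse = mean(calc - exp)`.
#' @export
errorMetrics <- function(expVals, calcVals) {
  expVals <- assertFinite(expVals, "expVals")
  calcVals <- assertFinite(calcVals, "calcVals")
  if (length(expVals) != length(calcVals)) stop("inputs must have equal length")
  if (length(expVals) < 1L) stop("inputs must be non-empty")
  d <- calcVals - expVals
  list(mue = mean(abs(d)), mse = mean(d))
}

#' Systematic offset of one compound across its alchemical pairs
#'
#' Mean discrepancy `ddG_calc - ddG_exp` over all pairs involving the named
#' compound, with each pair oriented so the compound sits on the "to" side
#' (reversing a pair negates both ddG values, so the oriented discrepancy
#' is direction-invariant).  A consistently positive offset means the
#' calculations place the compound's binding that many kcal/mol less
#' favorable, relative to experiment, than its partners.
#'
#' @param compound Compound label.
#' @param pairResults Data frame with columns `from`, `to`, `ddg_calc`,
#'   `ddg_exp` (ddG oriented from -> to).
#' @return Mean oriented discrepancy in kcal/mol.
#' @export
outlierOffset <- function(compound, pairResults) {
  need <- c("from", "to", "ddg_calc", "ddg_exp")
  if (!all(need %in% names(pairResults)))
    stop("'pairResults' needs columns ", paste(need, collapse = ", "))
  hit <- pairResults$from == compound | pairResults$to == compound
  if (!any(hit)) stop(sprintf("compound '%s' appears in no pair", compound))
  p <- pairResults[hit, , drop = FALSE]
  disc <- p$ddg_calc - p$ddg_exp
  orient <- ifelse(p$to == compound, 1, -1)
  mean(orient * disc)
}

#' Agreement between two independent calculation sets
#'
#' Compares per-compound estimates from two platforms or protocols:
#' mean signed and unsigned differences (B - A) and the fractions of
#' compounds whose difference lies within one and two combined error bars,
#' where the combined error bar is `sqrt(seA^2 + seB^2)`.
#'
#' @param setA,setB Data frames with columns `compound_id`, `value`, `se`.
#' @return List with `meanSigned`, `meanUnsigned`, `fracWithin1SE`,
#'   `fracWithin2SE`, `n`.
#' @export
crossPlatformAgreement <- function(setA, setB) {
  need <- c("compound_id", "value", "se")
  if (!all(need %in% names(setA)) || !all(need %in% names(setB)))
    stop("both sets need columns ", paste(need, collapse = ", "))
  if (!setequal(setA$compound_id, setB$compound_id) ||
      anyDuplicated(setA$compound_id) || anyDuplicated(setB$compound_id))
    stop("compound ids must match one-to-one between sets")
  b <- setB[match(setA$compound_id, setB$compound_id), , drop = FALSE]
  d <- b$value - setA$value
  bar <- sqrt(setA$se^2 + b$se^2)
  list(meanSigned = mean(d), meanUnsigned = mean(abs(d)),
       fracWithin1SE = mean(abs(d) <= bar),
       fracWithin2SE = mean(abs(d) <= 2 * bar),
       n = length(d))
}

#' Stratify calculated free energies by compound net charge
#'
#' Group means of the calculated values per net-charge stratum, plus a
#' flag for whether the charged compounds' mean is more favorable (more
#' negative) than the neutral compounds' mean -- the qualitative
#' distinction a correct electrostatic model should reproduce.
#'
#' @param records Data frame with columns `compound_id`, `net_charge`.
#' @param estimates Data frame with columns `compound_id`, `value`
#'   (kcal/mol).
#' @return List with `summary` (data frame: `net_charge`, `n`, `mean`) and
#'   `chargedMoreFavorable` (`TRUE`/`FALSE`, or `NA` when only one stratum
#'   is present).
#' @export
stratifyByCharge <- function(records, estimates) {
  if (!all(c("compound_id", "net_charge") %in% names(records)))
    stop("'records' needs columns compound_id, net_charge")
  if (!all(c("compound_id", "value") %in% names(estimates)))
    stop("'estimates' needs columns compound_id, value")
  if (any(is.na(records$net_charge)))
    stop("net_charge must be present for all records")
  m <- merge(records[, c("compound_id", "net_charge")],
             estimates[, c("compound_id", "value")], by = "compound_id")
  agg <- stats::aggregate(value ~ net_charge, data = m,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  summary <- data.frame(net_charge = agg$net_charge,
                        n = agg$value[, "n"], mean = agg$value[, "mean"])
  summary <- summary[summary$n > 0, , drop = FALSE]
  flag <- NA
  if (nrow(summary) > 1L && any(summary$net_charge == 0) &&
      any(summary$net_charge != 0)) {
    chargedMean <- mean(m$value[m$net_charge != 0])
    neutralMean <- mean(m$value[m$net_charge == 0])
    flag <- chargedMean < neutralMean
  }
  list(summary = summary, chargedMoreFavorable = flag)
}

# ---------------------------------------------------------------------------
# ComparisonReport
# ---------------------------------------------------------------------------

#' ComparisonReport: calculation-versus-experiment agreement summary
#'
#' @slot pearson,spearman Correlation point estimates.
#' @slot pearsonCI,spearmanCI 95% confidence intervals.
#' @slot mue,mse Mean unsigned/signed error (kcal/mol, calc - exp).
#' @slot nPairs Number of compound pairs entering the statistics.
#' @slot slope,intercept Ordinary least-squares line of calc on exp.
#' @slot excludedIds Compounds excluded (censored measurements).
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  slots = c(pearson = "numeric", pearsonCI = "numeric",
            spearman = "numeric", spearmanCI = "numeric",
            mue = "numeric", mse = "numeric", nPairs = "integer",
            slope = "numeric", intercept = "numeric",
            excludedIds = "character"))

setValidity("ComparisonReport", function(object) {
  msg <- character()
  for (nm in c("pearson", "spearman")) {
    r <- slot(object, nm)
    ci <- slot(object, paste0(nm, "CI"))
    if (abs(r) > 1 + 1e-12) msg <- c(msg, paste(nm, "out of [-1, 1]"))
    if (length(ci) == 2L && (r < ci[1L] - 1e-9 || r > ci[2L] + 1e-9))
      msg <- c(msg, paste(nm, "CI must bracket the point estimate"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", object@nPairs, "compounds\n")
  cat(sprintf("  Pearson  %.2f [CI: %.2f-%.2f]\n", object@pearson,
              object@pearsonCI[1L], object@pearsonCI[2L]))
  cat(sprintf("  Spearman %.2f [CI: %.2f-%.2f]\n", object@spearman,
              object@spearmanCI[1L], object@spearmanCI[2L]))
  cat(sprintf("  MUE %.2f kcal/mol, MSE %.2f kcal/mol\n",
              object@mue, object@mse))
  cat(sprintf("  OLS calc ~ exp: slope %.2f, intercept %.2f\n",
              object@slope, object@intercept))
  if (length(object@excludedIds))
    cat("  excluded (censored):", paste(object@excludedIds, collapse = ", "),
        "\n")
})

#' Full calculation-versus-experiment comparison
#'
#' Computes Pearson and Spearman correlations (with bootstrap CIs), mean
#' unsigned/signed errors and an OLS regression line between experimental
#' and calculated binding free energies.  Compounds flagged as censored
#' (assay reported only "no activity at the highest concentration", so the
#' experimental value is a bound, not a measurement) are excluded from the
#' fitted statistics by default and listed in `excludedIds`.  Note that
#' with non-normal errors the regression line should not be corrected for
#' regression dilution.
#'
#' @param records Data frame with `compound_id`, an experimental value
#'   (`dg_exp`, or `pIC50` which is converted at `temperatureK`), and an
#'   optional logical/0-1 `censored` column.
#' @param estimates Data frame with `compound_id`, `value` (calculated
#'   kcal/mol).
#' @param includeCensored Keep censored compounds in the statistics.
#' @param nBoot,seed Bootstrap settings for the correlation CIs.
#' @param temperatureK Temperature for the pIC50 conversion.
#' @return A [ComparisonReport-class].
#' @export
comparisonReport <- function(records, estimates, includeCensored = FALSE,
                             nBoot = 10000, seed = 42, temperatureK = 300) {
  if (!("compound_id" %in% names(records)))
    stop("'records' needs a compound_id column")
  if (!all(c("compound_id", "value") %in% names(estimates)))
    stop("'estimates' needs columns compound_id, value")
  if (!("dg_exp" %in% names(records))) {
    if (!("pIC50" %in% names(records)))
      stop("'records' needs a dg_exp or pIC50 column")
    records$dg_exp <- pic50ToDg(records$pIC50, temperatureK)
  }
  censored <- if ("censored" %in% names(records))
    as.logical(records$censored) else rep(FALSE, nrow(records))
  excluded <- character()
  keep <- rep(TRUE, nrow(records))
  if (!includeCensored) {
    keep <- !censored
    excluded <- records$compound_id[censored]
  }
  m <- merge(records[keep, c("compound_id", "dg_exp")],
             estimates[, c("compound_id", "value")], by = "compound_id")
  if (nrow(m) < 4L) stop("fewer than 4 usable compound pairs")
  pe <- correlationWithCI(m$dg_exp, m$value, "pearson", nBoot, seed)
  sp <- correlationWithCI(m$dg_exp, m$value, "spearman", nBoot, seed + 1L)
  em <- errorMetrics(m$dg_exp, m$value)
  fit <- stats::lm(value ~ dg_exp, data = m)
  new("ComparisonReport",
      pearson = pe$estimate, pearsonCI = pe$ci,
      spearman = sp$estimate, spearmanCI = sp$ci,
      mue = em$mue, mse = em$mse, nPairs = nrow(m),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      excludedIds = as.character(excluded))
}
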