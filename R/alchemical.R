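# Alchemical (TI) stage: per-window ensemble averages of dV/dlambda,
# trapezoidal integration over the lambda schedule per replica, and
# assembly of relative binding free energies from the two legs.

#' Default lambda schedule for thermodynamic integration
#'
#' The fixed 13-window schedule: dense (0.05-spaced) near the endpoints,
#' where the integrand changes fastest under soft-core/charge-scaling
#' protocols, and 0.1-spaced in between.
#'
#' @return `c(0, 0.05, 0.1, 0.2, ..., 0.9, 0.95, 1)`.
#' @export
defaultLambdaSchedule <- function() {
  c(0, 0.05, seq(0.1, 0.9, by = 0.1), 0.95, 1)
}

#' Ensemble average of one lambda window
#'
#' Per-replica sample means of `dV/dlambda`, their ensemble mean, and a
#' replica-bootstrap standard error.
#'
#' @param samples Numeric matrix (samples x replicas), or vector for a
#'   single replica.
#' @param nBoot,seed Bootstrap settings, see [bootstrapSE()].
#' @return List with `perReplica`, `mean` and `se`.
#' @export
windowAverage <- function(samples, nBoot = 1000, seed = 42) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("'samples' must contain at least one sample for one replica")
  assertFinite(samples, "samples")
  perRep <- colMeans(samples)
  se <- if (length(perRep) > 1L) bootstrapSE(perRep, nBoot, seed) else 0
  list(perReplica = perRep, mean = mean(perRep), se = se)
}

# Per-replica window means for the replicas common to all windows.
.legReplicaMeans <- function(leg, strict) {
  idSets <- lapply(windowSamples(leg), colnames)
  common <- Reduce(intersect, idSets)
  all <- unique(unlist(idSets))
  if (length(common) == 0L)
    stop("no replica is present in every lambda window")
  if (length(common) < length(all)) {
    dropped <- setdiff(all, common)
    msg <- sprintf("replica(s) %s missing from some windows",
                   paste(dropped, collapse = ", "))
    if (strict) stop(msg, " (strict mode)")
    warning(msg, "; excluded from all windows")
  }
  m <- vapply(windowSamples(leg),
              function(w) colMeans(w[, common, drop = FALSE]),
              numeric(length(common)))
  # windows x replicas
  matrix(t(m), ncol = length(common), dimnames = list(NULL, common))
}

#' Thermodynamic integration over a lambda schedule
#'
#' For each replica, integrates that replica's window means over lambda by
#' the trapezoidal rule on the schedule nodes; the estimate is the mean of
#' the per-replica integrals and the standard error their replica
#' bootstrap.  Integrating per replica before averaging yields the same
#' point estimate as averaging first (the quadrature is linear) while
#' providing the per-replica integral distribution the bootstrap resamples.
#'
#' @param leg A [LambdaLeg-class].
#' @param nBoot,seed Bootstrap settings.
#' @param strict If `TRUE`, a replica missing from any window is an error;
#'   otherwise it is dropped from all windows with a warning.
#' @return A [FreeEnergyEstimate-class] with mode `"ti"`.
#' @examples
#' leg <- simulateLambdaSamples(c(0, 2), noiseSd = 0)
#' feValue(tiIntegrate(leg))  # 1: trapezoid is exact for linear integrands
#' @export
tiIntegrate <- function(leg, nBoot = 1000, seed = 42, strict = FALSE) {
  if (!is(leg, "LambdaLeg")) stop("'leg' must be a LambdaLeg")
  means <- .legReplicaMeans(leg, strict)
  lam <- lambdaSchedule(leg)
  perRep <- apply(means, 2L, function(y) trapezoid(lam, y))
  se <- if (length(perRep) > 1L) bootstrapSE(perRep, nBoot, seed) else 0
  notes <- if (length(perRep) == 1L) "single replica: se degenerate at 0"
           else character()
  FreeEnergyEstimate(mean(perRep), se, perRep,
                     nFramesPerReplica = nrow(windowSamples(leg)[[1L]]),
                     mode = "ti", notes = notes)
}

#' Relative binding free energy from two alchemical legs
#'
#' Assembles `ddG = dG_complex - dG_aqueous` from the TI estimates of the
#' complex and aqueous legs of one alchemical transformation, combining the
#' leg standard errors in quadrature (the legs are independent
#' simulations).  Pairs whose endpoints carry different net charges are
#' refused: alchemical transformations that change the net charge require
#' charge corrections that are not implemented here.
#'
#' @param complexLeg,aqueousLeg [LambdaLeg-class] objects with matching
#'   `pairId`.
#' @param netCharge Optional numeric vector `c(from, to)` of the two
#'   compounds' net charges; unequal values are an error.
#' @param nBoot,seed,strict Passed to [tiIntegrate()] (seed offset by one
#'   between legs so their bootstrap draws are independent).
#' @return A [RelativeEstimate-class].
#' @export
tiesEstimate <- function(complexLeg, aqueousLeg, netCharge = NULL,
                         nBoot = 1000, seed = 42, strict = FALSE) {
  if (!is(complexLeg, "LambdaLeg") || !is(aqueousLeg, "LambdaLeg"))
    stop("legs must be LambdaLeg objects")
  if (legLabel(complexLeg) != "complex" || legLabel(aqueousLeg) != "aqueous")
    stop("legs must be labelled 'complex' and 'aqueous' respectively")
  if (pairId(complexLeg) != pairId(aqueousLeg))
    stop(sprintf("legs describe different compound pairs: '%s' vs '%s'",
                 pairId(complexLeg), pairId(aqueousLeg)))
  if (!is.null(netCharge)) {
    if (length(netCharge) != 2L)
      stop("'netCharge' must be c(from, to)")
    if (netCharge[1L] != netCharge[2L])
      stop("compounds in a pair must share the same net charge; no charge correction is implemented")
  }
  dgC <- tiIntegrate(complexLeg, nBoot, seed, strict)
  dgA <- tiIntegrate(aqueousLeg, nBoot, seed + 1L, strict)
  pair <- strsplit(pairId(complexLeg), "->", fixed = TRUE)[[1L]]
  if (length(pair) != 2L) pair <- c(pairId(complexLeg), pairId(complexLeg))
  new("RelativeEstimate", ddg = dgC@value - dgA@value,
      se = sqrt(dgC@se^2 + dgA@se^2), dgComplex = dgC, dgAqueous = dgA,
      pair = pair)
}
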