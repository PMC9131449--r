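# Endpoint (ESMACS/MMPBSA-style) stage: aggregate per-frame energies of
# complex, protein and ligand ensembles into a binding free energy with a
# replica-bootstrap standard error.

#' Per-frame MMPBSA-style free energy
#'
#' Sum of the gas-phase molecular-mechanics energy and the polar
#' (Poisson-Boltzmann) and nonpolar (surface-area) solvation terms, in
#' kcal/mol.  The configurational-entropy term is deliberately never added:
#' its contribution rarely improves affinity rankings and it is excluded
#' from this endpoint estimate.
#'
#' @param mm Gas-phase molecular-mechanics energy (kcal/mol).
#' @param polarSolv Polar solvation free energy (kcal/mol).
#' @param nonpolarSolv Nonpolar solvation free energy (kcal/mol).
#' @return `mm + polarSolv + nonpolarSolv`, vectorized.
#' @examples
#' mmpbsaFrameEnergy(-50, -30, 5)  # -75
#' @export
mmpbsaFrameEnergy <- function(mm, polarSolv, nonpolarSolv) {
  mm <- assertFinite(mm, "mm")
  polarSolv <- assertFinite(polarSolv, "polarSolv")
  nonpolarSolv <- assertFinite(nonpolarSolv, "nonpolarSolv")
  mm + polarSolv + nonpolarSolv
}

#' Replica-bootstrap standard error of an ensemble mean
#'
#' Resamples the per-replica values with replacement and reports the
#' standard deviation of the bootstrap distribution of the mean.  The
#' bootstrap unit is the replica, not the frame: frames within a replica
#' are autocorrelated, while replicas (independent initial velocities) are
#' the exchangeable unit of the ensemble protocol.
#'
#' @param perReplica Numeric vector of per-replica values (kcal/mol).
#' @param nBoot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return Standard error (kcal/mol).  A single replica yields 0 with a
#'   warning, as no between-replica variability can be estimated.
#' @export
bootstrapSE <- function(perReplica, nBoot = 1000, seed = 42) {
  perReplica <- assertFinite(perReplica, "perReplica")
  nBoot <- assertCount(nBoot, "nBoot")
  n <- length(perReplica)
  if (n < 1L) stop("'perReplica' must be non-empty")
  if (n == 1L) {
    warning("single replica: bootstrap SE reported as 0")
    return(0)
  }
  withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
    stats::sd(rowMeans(matrix(perReplica[idx], nrow = nBoot)))
  })
}

.checkMatchedEnsembles <- function(com, pro, lig) {
  ids <- replicaIds(com)
  if (!identical(ids, replicaIds(pro)) || !identical(ids, replicaIds(lig)))
    stop("one_trajectory mode requires matching replica ids across components")
  if (nFrames(com) != nFrames(pro) || nFrames(com) != nFrames(lig))
    stop("one_trajectory mode requires matching frame counts across components")
}

#' Ensemble endpoint binding free-energy estimate
#'
#' Aggregates per-frame energies of the complex, protein and ligand
#' ensembles into a binding free energy `dG = G_complex - G_protein -
#' G_ligand`.  In `one_trajectory` mode (the default, matching the
#' protocol in which protein and ligand conformations are extracted from
#' the complex trajectory) the difference is taken frame by frame within
#' each replica, the frame means give per-replica values, and their mean is
#' the estimate; this equals the difference of component means but defines
#' the per-replica values the bootstrap needs.  In `three_trajectory` mode
#' the three ensembles are averaged independently (no frame matching) and
#' leg SEs combine in quadrature.
#'
#' @param complexEns,proteinEns,ligandEns [EnergyEnsemble-class] objects
#'   for the three component roles.
#' @param mode `"one_trajectory"` or `"three_trajectory"`.
#' @param nBoot,seed Bootstrap settings, see [bootstrapSE()].
#' @return A [FreeEnergyEstimate-class].
#' @examples
#' tr <- simulateReplicaTraces(10, 50)
#' esmacsEstimate(tr$ensembles$complex, tr$ensembles$protein,
#'                tr$ensembles$ligand)
#' @export
esmacsEstimate <- function(complexEns, proteinEns, ligandEns,
                           mode = c("one_trajectory", "three_trajectory"),
                           nBoot = 1000, seed = 42) {
  mode <- match.arg(mode)
  for (e in list(complexEns, proteinEns, ligandEns))
    if (!is(e, "EnergyEnsemble")) stop("inputs must be EnergyEnsemble objects")
  if (mode == "one_trajectory") {
    .checkMatchedEnsembles(complexEns, proteinEns, ligandEns)
    dgFrames <- frameEnergies(complexEns) - frameEnergies(proteinEns) -
      frameEnergies(ligandEns)
    perRep <- colMeans(dgFrames)
    se <- if (length(perRep) > 1L) bootstrapSE(perRep, nBoot, seed) else 0
    notes <- if (length(perRep) == 1L) "single replica: se degenerate at 0"
             else character()
    FreeEnergyEstimate(mean(perRep), se, perRep,
                       nFramesPerReplica = nFrames(complexEns),
                       mode = mode, notes = notes)
  } else {
    means <- lapply(list(complexEns, proteinEns, ligandEns),
                    function(e) colMeans(frameEnergies(e)))
    ses <- vapply(seq_along(means), function(i) {
      if (length(means[[i]]) > 1L) bootstrapSE(means[[i]], nBoot, seed + i - 1L)
      else 0
    }, numeric(1L))
    # per-replica values anchored on the complex ensemble so their mean is
    # the estimate; the SE still combines all three legs
    perRep <- means[[1L]] - mean(means[[2L]]) - mean(means[[3L]])
    FreeEnergyEstimate(mean(perRep), sqrt(sum(ses^2)), perRep,
                       nFramesPerReplica = nFrames(complexEns), mode = mode)
  }
}

#' Adaptation free energy of the protein
#'
#' Difference between the mean protein free energy in the bound state and
#' in the free state: a measure of the conformational strain induced in
#' the protein by ligand binding.  Standard errors of the two independent
#' ensembles are combined in quadrature.
#'
#' @param proteinBoundEns,proteinFreeEns [EnergyEnsemble-class] objects for
#'   the protein extracted from the bound-state and free-state ensembles.
#' @param nBoot,seed Bootstrap settings.
#' @return A [FreeEnergyEstimate-class] with mode `"adaptation"`.
#' @export
adaptationFreeEnergy <- function(proteinBoundEns, proteinFreeEns,
                                 nBoot = 1000, seed = 42) {
  for (e in list(proteinBoundEns, proteinFreeEns))
    if (!is(e, "EnergyEnsemble")) stop("inputs must be EnergyEnsemble objects")
  mb <- colMeans(frameEnergies(proteinBoundEns))
  mf <- colMeans(frameEnergies(proteinFreeEns))
  seB <- if (length(mb) > 1L) bootstrapSE(mb, nBoot, seed) else 0
  seF <- if (length(mf) > 1L) bootstrapSE(mf, nBoot, seed + 1L) else 0
  perRep <- mb - mean(mf)
  FreeEnergyEstimate(mean(mb) - mean(mf), sqrt(seB^2 + seF^2), perRep,
                     nFramesPerReplica = nFrames(proteinBoundEns),
                     mode = "adaptation")
}

#' Add an adaptation term to an endpoint estimate
#'
#' Shifts an endpoint binding free-energy estimate by the adaptation free
#' energy, combining standard errors in quadrature.
#'
#' @param estimate A [FreeEnergyEstimate-class] from [esmacsEstimate()].
#' @param adaptation A [FreeEnergyEstimate-class] from
#'   [adaptationFreeEnergy()].
#' @return A [FreeEnergyEstimate-class] with `adaptationIncluded = TRUE`.
#' @export
includeAdaptation <- function(estimate, adaptation) {
  if (!is(estimate, "FreeEnergyEstimate") || !is(adaptation, "FreeEnergyEstimate"))
    stop("both arguments must be FreeEnergyEstimate objects")
  FreeEnergyEstimate(estimate@value + adaptation@value,
                     sqrt(estimate@se^2 + adaptation@se^2),
                     estimate@perReplica + adaptation@value,
                     nFramesPerReplica = estimate@nFramesPerReplica,
                     mode = estimate@mode, adaptationIncluded = TRUE,
                     notes = estimate@notes)
}
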