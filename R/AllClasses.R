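#' @import methods
NULL

.ROLES <- c("complex", "protein", "ligand")
.LEGS <- c("aqueous", "complex")

# ---------------------------------------------------------------------------
# EnergyEnsemble
# ---------------------------------------------------------------------------

#' EnergyEnsemble: per-frame endpoint energies for one system component
#'
#' Holds the per-frame total free-energy values (kcal/mol) of every replica
#' of an ensemble of molecular-dynamics simulations, for one component role
#' (`complex`, `protein` or `ligand`).  Frames are rows, replicas columns;
#' column names are replica identifiers.  The total may optionally be
#' decomposed into the gas-phase molecular-mechanics energy (`e_mm`), the
#' polar (Poisson-Boltzmann) solvation term (`g_polar`) and the nonpolar
#' (surface-area) solvation term (`g_nonpolar`); when present the three
#' components must sum to the total within 1e-6 kcal/mol.
#'
#' @slot role Component role, one of `"complex"`, `"protein"`, `"ligand"`.
#' @slot frames Numeric matrix, `n_frames x n_replicas`, of total energies.
#' @slot components Named list of matrices (`e_mm`, `g_polar`, `g_nonpolar`)
#'   with the same dimensions as `frames`, or an empty list.
#' @slot metadata Free-form list (generator truth records live here).
#' @exportClass EnergyEnsemble
setClass("EnergyEnsemble",
  slots = c(role = "character", frames = "matrix",
            components = "list", metadata = "list"))

setValidity("EnergyEnsemble", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !(object@role %in% .ROLES))
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.ROLES, collapse = ", ")))
  fr <- object@frames
  if (!is.numeric(fr) || nrow(fr) < 1L || ncol(fr) < 1L)
    msg <- c(msg, "frames must be a numeric matrix with >= 1 frame and replica")
  else if (!all(is.finite(fr)))
    msg <- c(msg, "all frame energies must be finite")
  if (length(object@components)) {
    need <- c("e_mm", "g_polar", "g_nonpolar")
    if (!setequal(names(object@components), need))
      msg <- c(msg, "components must be named e_mm, g_polar, g_nonpolar")
    else {
      tot <- object@components$e_mm + object@components$g_polar +
        object@components$g_nonpolar
      if (!isTRUE(all(dim(tot) == dim(fr))))
        msg <- c(msg, "component matrices must match frames in dimension")
      else if (max(abs(tot - fr)) > 1e-6)
        msg <- c(msg, "energy components must sum to the total within 1e-6")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EnergyEnsemble
#'
#' @param frames Numeric matrix (frames x replicas) of total energies in
#'   kcal/mol; a vector is taken as a single replica.
#' @param role Component role: `"complex"`, `"protein"` or `"ligand"`.
#' @param components Optional named list of `e_mm`, `g_polar`, `g_nonpolar`
#'   matrices summing to `frames`.
#' @param metadata Optional list carried along unchanged.
#' @return An [EnergyEnsemble-class] object.
#' @export
EnergyEnsemble <- function(frames, role, components = list(),
                           metadata = list()) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (is.null(colnames(frames)))
    colnames(frames) <- sprintf("rep%02d", seq_len(ncol(frames)))
  new("EnergyEnsemble", role = role, frames = frames,
      components = components, metadata = metadata)
}

#' @describeIn EnergyEnsemble Number of replicas.
#' @param x,object An `EnergyEnsemble`.
#' @export
setGeneric("nReplicas", function(x) standardGeneric("nReplicas"))

#' @rdname EnergyEnsemble
#' @export
setMethod("nReplicas", "EnergyEnsemble", function(x) ncol(x@frames))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname EnergyEnsemble
#' @export
setMethod("nFrames", "EnergyEnsemble", function(x) nrow(x@frames))

#' @export
setGeneric("replicaIds", function(x) standardGeneric("replicaIds"))

#' @rdname EnergyEnsemble
#' @export
setMethod("replicaIds", "EnergyEnsemble", function(x) colnames(x@frames))

#' @export
setGeneric("frameEnergies", function(x) standardGeneric("frameEnergies"))

#' @rdname EnergyEnsemble
#' @export
setMethod("frameEnergies", "EnergyEnsemble", function(x) x@frames)

#' @export
setGeneric("componentRole", function(x) standardGeneric("componentRole"))

#' @rdname EnergyEnsemble
#' @export
setMethod("componentRole", "EnergyEnsemble", function(x) x@role)

setMethod("show", "EnergyEnsemble", function(object) {
  cat(sprintf("EnergyEnsemble (%s): %d replicas x %d frames\n",
              object@role, ncol(object@frames), nrow(object@frames)))
  cat(sprintf("  mean G: %.3f kcal/mol; components: %s\n",
              mean(object@frames),
              if (length(object@components)) "decomposed" else "total only"))
})

# ---------------------------------------------------------------------------
# FreeEnergyEstimate
# ---------------------------------------------------------------------------

#' FreeEnergyEstimate: ensemble binding free-energy estimate
#'
#' Point estimate with replica-bootstrap standard error.  `perReplica`
#' holds one value per replica; the estimate is their mean (within 1e-9).
#'
#' @slot value Estimate in kcal/mol.
#' @slot se Bootstrap standard error in kcal/mol (0 for a single replica).
#' @slot perReplica Named numeric vector of per-replica values.
#' @slot nFramesPerReplica Frames averaged per replica (NA if unknown/mixed).
#' @slot mode `"one_trajectory"`, `"three_trajectory"`, `"adaptation"` or
#'   `"ti"`.
#' @slot adaptationIncluded Whether an adaptation term has been added.
#' @slot notes Character vector of warnings attached to the estimate.
#' @exportClass FreeEnergyEstimate
setClass("FreeEnergyEstimate",
  slots = c(value = "numeric", se = "numeric", perReplica = "numeric",
            nFramesPerReplica = "numeric", mode = "character",
            adaptationIncluded = "logical", notes = "character"))

setValidity("FreeEnergyEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1L || !is.finite(object@value))
    msg <- c(msg, "value must be a single finite number")
  if (length(object@se) != 1L || !is.finite(object@se) || object@se < 0)
    msg <- c(msg, "se must be a single finite number >= 0")
  if (length(object@perReplica) &&
      abs(object@value - mean(object@perReplica)) > 1e-9)
    msg <- c(msg, "value must equal the mean of perReplica within 1e-9")
  if (length(msg)) msg else TRUE
})

FreeEnergyEstimate <- function(value, se, perReplica,
                               nFramesPerReplica = NA_real_,
                               mode = "one_trajectory",
                               adaptationIncluded = FALSE,
                               notes = character()) {
  new("FreeEnergyEstimate", value = as.numeric(value), se = as.numeric(se),
      perReplica = perReplica, nFramesPerReplica = as.numeric(nFramesPerReplica),
      mode = mode, adaptationIncluded = adaptationIncluded, notes = notes)
}

#' @export
setGeneric("feValue", function(x) standardGeneric("feValue"))

#' @rdname FreeEnergyEstimate-class
#' @param x A `FreeEnergyEstimate`.
#' @export
setMethod("feValue", "FreeEnergyEstimate", function(x) x@value)

#' @export
setGeneric("feSE", function(x) standardGeneric("feSE"))

#' @rdname FreeEnergyEstimate-class
#' @export
setMethod("feSE", "FreeEnergyEstimate", function(x) x@se)

#' @export
setGeneric("perReplica", function(x) standardGeneric("perReplica"))

#' @rdname FreeEnergyEstimate-class
#' @export
setMethod("perReplica", "FreeEnergyEstimate", function(x) x@perReplica)

#' @rdname FreeEnergyEstimate-class
#' @export
setMethod("nReplicas", "FreeEnergyEstimate",
          function(x) length(x@perReplica))

setMethod("show", "FreeEnergyEstimate", function(object) {
  cat(sprintf("FreeEnergyEstimate [%s]: %.3f +/- %.3f kcal/mol (%d replicas)\n",
              object@mode, object@value, object@se, length(object@perReplica)))
  if (object@adaptationIncluded) cat("  includes adaptation free energy\n")
  for (n in object@notes) cat("  note:", n, "\n")
})

# ---------------------------------------------------------------------------
# LambdaLeg
# ---------------------------------------------------------------------------

#' LambdaLeg: per-window dV/dlambda samples for one alchemical leg
#'
#' One leg (aqueous or complex) of an alchemical transformation: for each
#' lambda window of the schedule, a matrix of `dV/dlambda` samples
#' (kcal/mol), samples as rows, replicas as columns.  The schedule must be
#' strictly increasing within \[0, 1\] and contain both endpoints, without
#' which the integral over \[0, 1\] is undefined.
#'
#' @slot leg `"aqueous"` or `"complex"`.
#' @slot pairId Label of the compound pair being transformed (e.g.
#'   `"S01->S02"`).
#' @slot lambdas Numeric vector of window positions.
#' @slot samples List (one per window) of numeric matrices, samples x
#'   replicas, with replica ids as column names.
#' @slot metadata Free-form list (generator truth records live here).
#' @exportClass LambdaLeg
setClass("LambdaLeg",
  slots = c(leg = "character", pairId = "character", lambdas = "numeric",
            samples = "list", metadata = "list"))

setValidity("LambdaLeg", function(object) {
  msg <- character()
  if (length(object@leg) != 1L || !(object@leg %in% .LEGS))
    msg <- c(msg, "leg must be 'aqueous' or 'complex'")
  l <- object@lambdas
  if (length(l) < 2L || anyDuplicated(l) || is.unsorted(l, strictly = TRUE) ||
      any(l < 0 | l > 1))
    msg <- c(msg, "lambdas must be unique, strictly increasing and in [0, 1]")
  else if (l[1L] != 0 || l[length(l)] != 1)
    msg <- c(msg, "lambda schedule must include both endpoints 0 and 1")
  if (length(object@samples) != length(l))
    msg <- c(msg, "need one sample matrix per lambda window")
  else {
    ok <- vapply(object@samples, function(m)
      is.matrix(m) && is.numeric(m) && nrow(m) >= 1L && ncol(m) >= 1L &&
        all(is.finite(m)), logical(1L))
    if (!all(ok))
      msg <- c(msg, "every window needs a finite sample matrix with >= 1 replica")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LambdaLeg
#'
#' @param lambdas Window positions in \[0, 1\] including 0 and 1.
#' @param samples List of samples-by-replicas matrices, one per window.
#' @param leg `"aqueous"` or `"complex"`.
#' @param pairId Compound-pair label.
#' @param metadata Optional list.
#' @return A [LambdaLeg-class] object.
#' @export
LambdaLeg <- function(lambdas, samples, leg = "complex", pairId = "A->B",
                      metadata = list()) {
  samples <- lapply(samples, function(m) {
    if (is.vector(m)) m <- matrix(m, ncol = 1L)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (is.null(colnames(m)))
      colnames(m) <- sprintf("rep%02d", seq_len(ncol(m)))
    m
  })
  new("LambdaLeg", leg = leg, pairId = pairId,
      lambdas = as.numeric(lambdas), samples = samples, metadata = metadata)
}

#' @export
setGeneric("lambdaSchedule", function(x) standardGeneric("lambdaSchedule"))

#' @rdname LambdaLeg-class
#' @param x A `LambdaLeg`.
#' @export
setMethod("lambdaSchedule", "LambdaLeg", function(x) x@lambdas)

#' @export
setGeneric("windowSamples", function(x) standardGeneric("windowSamples"))

#' @rdname LambdaLeg-class
#' @export
setMethod("windowSamples", "LambdaLeg", function(x) x@samples)

#' @export
setGeneric("legLabel", function(x) standardGeneric("legLabel"))

#' @rdname LambdaLeg-class
#' @export
setMethod("legLabel", "LambdaLeg", function(x) x@leg)

#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname LambdaLeg-class
#' @export
setMethod("pairId", "LambdaLeg", function(x) x@pairId)

setMethod("show", "LambdaLeg", function(object) {
  reps <- unique(unlist(lapply(object@samples, colnames)))
  cat(sprintf("LambdaLeg [%s] %s: %d windows, %d replicas, %d samples/window\n",
              object@leg, object@pairId, length(object@lambdas),
              length(reps), nrow(object@samples[[1L]])))
})

# ---------------------------------------------------------------------------
# RelativeEstimate
# ---------------------------------------------------------------------------

#' RelativeEstimate: relative binding free energy from two alchemical legs
#'
#' The binding free-energy difference between two compounds, assembled as
#' the complex-leg alchemical free energy minus the aqueous-leg one, with
#' leg standard errors combined in quadrature.
#'
#' @slot ddg Relative binding free energy in kcal/mol.
#' @slot se Combined standard error in kcal/mol.
#' @slot dgComplex,dgAqueous Per-leg [FreeEnergyEstimate-class] objects.
#' @slot pair Character vector `c(from, to)`.
#' @exportClass RelativeEstimate
setClass("RelativeEstimate",
  slots = c(ddg = "numeric", se = "numeric",
            dgComplex = "FreeEnergyEstimate",
            dgAqueous = "FreeEnergyEstimate", pair = "character"))

setValidity("RelativeEstimate", function(object) {
  msg <- character()
  if (abs(object@ddg - (object@dgComplex@value - object@dgAqueous@value)) > 1e-9)
    msg <- c(msg, "ddg must equal dgComplex - dgAqueous within 1e-9")
  if (object@se < 0) msg <- c(msg, "se must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("ddG", function(x) standardGeneric("ddG"))

#' @rdname RelativeEstimate-class
#' @param x A `RelativeEstimate`.
#' @export
setMethod("ddG", "RelativeEstimate", function(x) x@ddg)

#' @rdname RelativeEstimate-class
#' @export
setMethod("feSE", "RelativeEstimate", function(x) x@se)

setMethod("show", "RelativeEstimate", function(object) {
  cat(sprintf("RelativeEstimate %s -> %s: ddG = %.3f +/- %.3f kcal/mol\n",
              object@pair[1L], object@pair[2L], object@ddg, object@se))
})

# ---------------------------------------------------------------------------
# AssayReplicates
# ---------------------------------------------------------------------------

#' AssayReplicates: repeated potency measurements for one compound
#'
#' @slot compoundId Compound label.
#' @slot values pIC50 measurements, in measurement order.
#' @slot timestamps Optional character vector of dates (same length as
#'   `values`, or empty).
#' @slot metadata Free-form list.
#' @exportClass AssayReplicates
setClass("AssayReplicates",
  slots = c(compoundId = "character", values = "numeric",
            timestamps = "character", metadata = "list"))

setValidity("AssayReplicates", function(object) {
  msg <- character()
  if (length(object@values) < 1L || !all(is.finite(object@values)))
    msg <- c(msg, "values must be non-empty and finite")
  if (length(object@timestamps) &&
      length(object@timestamps) != length(object@values))
    msg <- c(msg, "timestamps must be empty or match values in length")
  if (length(msg)) msg else TRUE
})

#' Construct an AssayReplicates set
#'
#' @param values pIC50 measurements in measurement order.
#' @param compoundId Compound label.
#' @param timestamps Optional dates (ISO-8601 strings).
#' @param metadata Optional list.
#' @return An [AssayReplicates-class] object.
#' @export
AssayReplicates <- function(values, compoundId = "compound",
                            timestamps = character(), metadata = list()) {
  new("AssayReplicates", compoundId = compoundId,
      values = as.numeric(values), timestamps = as.character(timestamps),
      metadata = metadata)
}

#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' @rdname AssayReplicates-class
#' @param x An `AssayReplicates` object.
#' @export
setMethod("assayValues", "AssayReplicates", function(x) x@values)

#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))

#' @rdname AssayReplicates-class
#' @export
setMethod("compoundId", "AssayReplicates", function(x) x@compoundId)

setMethod("show", "AssayReplicates", function(object) {
  cat(sprintf("AssayReplicates %s: %d measurements, mean pIC50 %.2f\n",
              object@compoundId, length(object@values), mean(object@values)))
})

# ---------------------------------------------------------------------------
# metadata accessor shared by the data classes
# ---------------------------------------------------------------------------

#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @rdname EnergyEnsemble
#' @export
setMethod("metadata", "EnergyEnsemble", function(x) x@metadata)

#' @rdname LambdaLeg-class
#' @export
setMethod("metadata", "LambdaLeg", function(x) x@metadata)

#' @rdname AssayReplicates-class
#' @export
setMethod("metadata", "AssayReplicates", function(x) x@metadata)
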