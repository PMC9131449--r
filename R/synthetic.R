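# Synthetic-data generators.
#
# Every generator is seed-deterministic and records the ground truth it was
# built from in the returned object's metadata (or as explicit columns), so
# downstream recovery tests never have to infer truth from the data.

# Stationary AR(1) series with marginal sd `sd` and lag-1 correlation `phi`.
ar1Series <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, 0, sd))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1L] <- stats::rnorm(1L, 0, sd)  # stationary start
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Fixed, exactly-summing decomposition of a total energy into MM + polar +
# nonpolar parts, so written tables exercise the component-sum invariant.
.decompose <- function(g) {
  list(e_mm = 0.7 * g, g_polar = 0.2 * g, g_nonpolar = 0.1 * g)
}

#' Simulate replica MD energy traces for the endpoint stage
#'
#' Emulates per-frame endpoint free energies of an ensemble of replica
#' simulations for each requested component role.  Each replica's frame
#' series is a stationary AR(1) process (lag-1 correlation `autocorr`,
#' marginal frame-to-frame SD `frameSd`) around a replica-level mean drawn
#' from `N(meanG[role], replicaSd^2)`.  The AR(1) structure reproduces the
#' frame autocorrelation that makes naive per-frame standard errors
#' optimistic and motivates replica-level bootstrapping.
#'
#' @param nReplicas,nFrames Ensemble dimensions (defaults follow the
#'   25-replica, 4 ns production protocol scale).
#' @param meanG Named numeric vector of true mean energies (kcal/mol), one
#'   per role, e.g. `c(complex = -100, protein = -60, ligand = -30)`.
#' @param frameSd Marginal SD of the frame series within a replica
#'   (kcal/mol, >= 0).
#' @param replicaSd SD of replica-level means about `meanG` (kcal/mol, >= 0).
#' @param autocorr AR(1) lag-1 correlation, in \[0, 1).
#' @param seed RNG seed (mandatory contract; default 42).
#' @return List with `ensembles` (named list of [EnergyEnsemble-class], one
#'   per role) and `truth` (list with `meanG` and, when the three standard
#'   roles are present, the implied ensemble-mean binding free energy `dg =
#'   meanG[complex] - meanG[protein] - meanG[ligand]`).  The same truth
#'   record is attached to each ensemble's metadata.
#' @examples
#' tr <- simulateReplicaTraces(5, 50,
#'   meanG = c(complex = -100, protein = -60, ligand = -30))
#' tr$truth$dg  # -10
#' @export
simulateReplicaTraces <- function(nReplicas = 25, nFrames = 200,
                                  meanG = c(complex = -100, protein = -60,
                                            ligand = -30),
                                  frameSd = 2, replicaSd = 0.5,
                                  autocorr = 0, seed = 42) {
  nReplicas <- assertCount(nReplicas, "nReplicas")
  nFrames <- assertCount(nFrames, "nFrames")
  frameSd <- assertNonNegative(frameSd, "frameSd")
  replicaSd <- assertNonNegative(replicaSd, "replicaSd")
  if (!is.numeric(autocorr) || autocorr < 0 || autocorr >= 1)
    stop("'autocorr' must be in [0, 1)")
  roles <- names(meanG)
  if (is.null(roles) || !all(roles %in% .ROLES))
    stop("'meanG' must be named with roles among complex, protein, ligand")
  truth <- list(meanG = meanG, frameSd = frameSd, replicaSd = replicaSd,
                autocorr = autocorr, seed = seed)
  if (all(.ROLES %in% roles))
    truth$dg <- unname(meanG["complex"] - meanG["protein"] - meanG["ligand"])
  ensembles <- withSeed(seed, {
    out <- list()
    for (role in roles) {
      repMeans <- meanG[[role]] + stats::rnorm(nReplicas, 0, replicaSd)
      fr <- vapply(seq_len(nReplicas), function(r)
        repMeans[r] + ar1Series(nFrames, frameSd, autocorr),
        numeric(nFrames))
      fr <- matrix(fr, nrow = nFrames)
      colnames(fr) <- sprintf("rep%02d", seq_len(nReplicas))
      out[[role]] <- EnergyEnsemble(fr, role,
                                    components = .decompose(fr),
                                    metadata = list(truth = truth))
    }
    out
  })
  list(ensembles = ensembles, truth = truth)
}

#' Simulate dV/dlambda samples for one alchemical leg
#'
#' Generates per-window `dV/dlambda` samples whose true window means follow
#' the polynomial `sum(coefficients[k] * lambda^(k-1))`, plus independent
#' Gaussian noise.  The analytic integral over \[0, 1\],
#' `sum(coefficients[k] / k)`, is recorded as ground truth.
#'
#' @param coefficients Polynomial coefficients of the true
#'   `<dV/dlambda>(lambda)` curve, constant term first (kcal/mol).
#' @param noiseSd SD of the sample noise about the true curve (>= 0).
#' @param nSamplesPerWindow,nReplicas Sampling dimensions.
#' @param schedule Lambda schedule; must be strictly increasing in \[0, 1\]
#'   with both endpoints present.
#' @param leg,pairId Leg label and compound-pair label for the result.
#' @param seed RNG seed.
#' @return A [LambdaLeg-class]; `metadata(x)$truth` holds `integral` and
#'   `coefficients`.
#' @examples
#' leg <- simulateLambdaSamples(c(0, 2), noiseSd = 0, nSamplesPerWindow = 1,
#'                              nReplicas = 1)
#' metadata(leg)$truth$integral  # 1: integral of 2*lambda over [0, 1]
#' @export
simulateLambdaSamples <- function(coefficients, noiseSd = 0.5,
                                  nSamplesPerWindow = 50, nReplicas = 5,
                                  schedule = defaultLambdaSchedule(),
                                  leg = "complex", pairId = "A->B",
                                  seed = 42) {
  coefficients <- assertFinite(coefficients, "coefficients")
  noiseSd <- assertNonNegative(noiseSd, "noiseSd")
  nSamplesPerWindow <- assertCount(nSamplesPerWindow, "nSamplesPerWindow")
  nReplicas <- assertCount(nReplicas, "nReplicas")
  if (any(schedule < 0 | schedule > 1) || is.unsorted(schedule, strictly = TRUE))
    stop("'schedule' must be strictly increasing within [0, 1]")
  if (schedule[1L] != 0 || schedule[length(schedule)] != 1)
    stop("'schedule' must contain both endpoints 0 and 1; the integral over [0, 1] is undefined otherwise")
  truthCurve <- vapply(schedule, function(l)
    sum(coefficients * l^(seq_along(coefficients) - 1L)), numeric(1L))
  truth <- list(
    integral = sum(coefficients / seq_along(coefficients)),
    coefficients = coefficients, noiseSd = noiseSd, seed = seed)
  samples <- withSeed(seed, lapply(truthCurve, function(mu) {
    m <- matrix(mu + stats::rnorm(nSamplesPerWindow * nReplicas, 0, noiseSd),
                nrow = nSamplesPerWindow)
    colnames(m) <- sprintf("rep%02d", seq_len(nReplicas))
    m
  }))
  LambdaLeg(schedule, samples, leg = leg, pairId = pairId,
            metadata = list(truth = truth))
}

#' Simulate skewed, heavy-tailed assay replicate measurements
#'
#' Draws repeated pIC50 measurements from a sinh-arcsinh transformed
#' location-scale family whose parameters are solved numerically so the
#' population mean, SD, skewness and excess kurtosis equal the request
#' (shape up to the family's attainable region; see
#' [solveSinhArcsinhShape()]).  An optional linear drift in measurement
#' index emulates slow assay drift over time.
#'
#' @param n Number of measurements.
#' @param mean,sd Target mean and SD of the underlying (drift-free)
#'   distribution, in pIC50 units.
#' @param skewness,excessKurtosis Target standardized moments.
#' @param driftPerIndex Added linear trend, pIC50 units per measurement
#'   index (value `i` gains `driftPerIndex * (i - 1)`).
#' @param compoundId Label for the resulting replicate set.
#' @param seed RNG seed.
#' @param shapeTol Relative tolerance on the attainable shape; see
#'   [solveSinhArcsinhShape()].
#' @return An [AssayReplicates-class]; `metadata(x)$truth` records the
#'   requested moments, the attained population shape, the drift and the
#'   solved family parameters.
#' @examples
#' a <- simulateAssayReplicates(200, mean = 7.09, sd = 0.21,
#'                              skewness = 2.11, excessKurtosis = 5.30)
#' summary(assayValues(a))
#' @export
simulateAssayReplicates <- function(n, mean = 7, sd = 0.2, skewness = 0,
                                    excessKurtosis = 0, driftPerIndex = 0,
                                    compoundId = "synthetic", seed = 42,
                                    shapeTol = 0.04) {
  n <- assertCount(n, "n")
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
  assertFinite(c(mean, driftPerIndex), "mean/driftPerIndex")
  sol <- solveSinhArcsinhShape(skewness, excessKurtosis, shapeTol)
  values <- withSeed(seed, {
    m <- sinhArcsinhMoments(sol$epsilon, sol$delta)
    z <- stats::rnorm(n)
    s <- sinh((asinh(z) + sol$epsilon) / sol$delta)
    mean + sd * (s - m[["mean"]]) / sqrt(m[["var"]])
  })
  values <- values + driftPerIndex * (seq_len(n) - 1L)
  truth <- list(mean = mean, sd = sd, skewness = skewness,
                excessKurtosis = excessKurtosis,
                attainedShape = sol$attained,
                driftPerIndex = driftPerIndex,
                epsilon = sol$epsilon, delta = sol$delta, seed = seed)
  AssayReplicates(values, compoundId = compoundId,
                  metadata = list(truth = truth))
}

#' Simulate a paired experimental/calculated compound set
#'
#' Builds a table of compounds with true binding free energies spread
#' evenly over `dgRange`, plus independently noised "experimental" and
#' "calculated" observations of each, for testing the comparison stage.
#' Optionally a systematic offset is injected into one compound's
#' calculated value, emulating an unexplained outlier.
#'
#' @param nCompounds Number of compounds (>= 3).
#' @param dgRange Range (kcal/mol) spanned by the true values.
#' @param expNoiseSd,calcNoiseSd SDs of the observation noise.
#' @param outlier Optional `list(index =, offset =)`: `offset` kcal/mol is
#'   added to the calculated value of compound `index`.
#' @param netCharges Optional integer vector of per-compound net charges
#'   (recycled); defaults to all 0.
#' @param seed RNG seed.
#' @return Data frame with columns `compound_id`, `net_charge`, `dg_true`,
#'   `dg_exp`, `dg_calc` (truth carried explicitly as `dg_true`).
#' @export
simulateCompoundSet <- function(nCompounds = 20, dgRange = c(-12, -6),
                                expNoiseSd = 0.3, calcNoiseSd = 0.6,
                                outlier = NULL, netCharges = 0L, seed = 42) {
  nCompounds <- assertCount(nCompounds, "nCompounds", min = 3L)
  expNoiseSd <- assertNonNegative(expNoiseSd, "expNoiseSd")
  calcNoiseSd <- assertNonNegative(calcNoiseSd, "calcNoiseSd")
  dgTrue <- seq(dgRange[1L], dgRange[2L], length.out = nCompounds)
  df <- withSeed(seed, data.frame(
    compound_id = sprintf("S%02d", seq_len(nCompounds)),
    net_charge = as.integer(rep_len(netCharges, nCompounds)),
    dg_true = dgTrue,
    dg_exp = dgTrue + stats::rnorm(nCompounds, 0, expNoiseSd),
    dg_calc = dgTrue + stats::rnorm(nCompounds, 0, calcNoiseSd),
    stringsAsFactors = FALSE))
  if (!is.null(outlier)) {
    if (!all(c("index", "offset") %in% names(outlier)))
      stop("'outlier' must be list(index =, offset =)")
    i <- assertCount(outlier$index, "outlier$index")
    if (i > nCompounds) stop("outlier index beyond compound set")
    df$dg_calc[i] <- df$dg_calc[i] + outlier$offset
  }
  df
}
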