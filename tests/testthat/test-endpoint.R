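# Endpoint aggregation: frame energies, ensemble estimates and the
# replica bootstrap.

test_that("frame energy is the exact sum of its three components", {
  expect_identical(mmpbsaFrameEnergy(0, 0, 0), 0)
  expect_identical(mmpbsaFrameEnergy(-50, -30, 5), -75)
  withr::with_seed(1, for (i in 1:50) {
    tr <- rnorm(3, 0, 100)
    expect_identical(mmpbsaFrameEnergy(tr[1], tr[2], tr[3]),
                     (tr[1] + tr[2]) + tr[3])
  })
  expect_error(mmpbsaFrameEnergy(NA, 0, 0), "finite")
  expect_error(mmpbsaFrameEnergy(Inf, 0, 0), "finite")
})

.toyEnsembles <- function(com, pro, lig) {
  list(EnergyEnsemble(com, "complex"), EnergyEnsemble(pro, "protein"),
       EnergyEnsemble(lig, "ligand"))
}

test_that("a degenerate single-frame ensemble reproduces the difference", {
  e <- .toyEnsembles(-100, -60, -30)
  est <- esmacsEstimate(e[[1]], e[[2]], e[[3]])
  expect_equal(feValue(est), -10)
  expect_identical(feSE(est), 0)
  expect_equal(nReplicas(est), 1L)
})

test_that("the estimate is invariant under replica permutation", {
  tr <- simulateReplicaTraces(8, 30, seed = 21)
  est <- esmacsEstimate(tr$ensembles$complex, tr$ensembles$protein,
                        tr$ensembles$ligand, seed = 1)
  perm <- withr::with_seed(2, sample(8))
  permute <- function(e) {
    m <- frameEnergies(e)[, perm]
    EnergyEnsemble(m, componentRole(e))
  }
  est2 <- esmacsEstimate(permute(tr$ensembles$complex),
                         permute(tr$ensembles$protein),
                         permute(tr$ensembles$ligand), seed = 1)
  expect_equal(feValue(est2), feValue(est))
  expect_equal(sort(perReplica(est2)), sort(unname(perReplica(est))),
               ignore_attr = TRUE)
})

test_that("shifting every complex frame by c shifts the estimate by c", {
  tr <- simulateReplicaTraces(6, 25, seed = 22)
  base <- esmacsEstimate(tr$ensembles$complex, tr$ensembles$protein,
                         tr$ensembles$ligand, seed = 1)
  shifted <- EnergyEnsemble(frameEnergies(tr$ensembles$complex) + 3.7,
                            "complex")
  est <- esmacsEstimate(shifted, tr$ensembles$protein, tr$ensembles$ligand,
                        seed = 1)
  expect_equal(feValue(est), feValue(base) + 3.7)
})

test_that("estimate equals the brute-force mean of frame differences", {
  withr::with_seed(31, for (i in 1:20) {
    nr <- sample(2:5, 1)
    nf <- sample(2:8, 1)
    com <- matrix(rnorm(nr * nf, -100, 5), nf)
    pro <- matrix(rnorm(nr * nf, -60, 5), nf)
    lig <- matrix(rnorm(nr * nf, -30, 5), nf)
    e <- .toyEnsembles(com, pro, lig)
    est <- esmacsEstimate(e[[1]], e[[2]], e[[3]], nBoot = 10, seed = 1)
    expect_equal(feValue(est), oracleEsmacs(com, pro, lig),
                 tolerance = 1e-9)
  })
})

test_that("mismatched replica structure is rejected in one-trajectory mode", {
  tr <- simulateReplicaTraces(4, 10, seed = 23)
  small <- EnergyEnsemble(frameEnergies(tr$ensembles$protein)[, 1:3],
                          "protein")
  expect_error(esmacsEstimate(tr$ensembles$complex, small,
                              tr$ensembles$ligand), "replica ids")
  short <- EnergyEnsemble(frameEnergies(tr$ensembles$protein)[1:5, ],
                          "protein")
  expect_error(esmacsEstimate(tr$ensembles$complex, short,
                              tr$ensembles$ligand), "frame counts")
})

test_that("three-trajectory mode equals the difference of ensemble means", {
  tr <- simulateReplicaTraces(5, 20, seed = 24)
  est <- esmacsEstimate(tr$ensembles$complex, tr$ensembles$protein,
                        tr$ensembles$ligand, mode = "three_trajectory",
                        seed = 1)
  expected <- mean(frameEnergies(tr$ensembles$complex)) -
    mean(frameEnergies(tr$ensembles$protein)) -
    mean(frameEnergies(tr$ensembles$ligand))
  expect_equal(feValue(est), expected, tolerance = 1e-12)
})

test_that("bootstrap SE is zero for identical replicas and matches 1/sqrt(n)", {
  expect_identical(bootstrapSE(rep(2.5, 10), seed = 1), 0)
  ses <- vapply(1:40, function(s)
    bootstrapSE(withr::with_seed(s, rnorm(25)), nBoot = 500, seed = s),
    numeric(1))
  expect_equal(mean(ses), 1 / sqrt(25), tolerance = 0.2)
})

test_that("a single replica yields zero SE with a warning", {
  expect_warning(se <- bootstrapSE(1.5), "single replica")
  expect_identical(se, 0)
})

test_that("adaptation free energy behaves as a constructed shift", {
  tr <- simulateReplicaTraces(6, 20, meanG = c(protein = -60), seed = 25)
  pro <- tr$ensembles$protein
  same <- adaptationFreeEnergy(pro, pro, seed = 1)
  expect_equal(feValue(same), 0, tolerance = 1e-12)
  shifted <- EnergyEnsemble(frameEnergies(pro) - 2, "protein")
  adapt <- adaptationFreeEnergy(pro, shifted, seed = 1)
  expect_equal(feValue(adapt), 2, tolerance = 1e-12)
})

test_that("adding the adaptation term shifts the estimate exactly", {
  tr <- simulateReplicaTraces(5, 15, seed = 26)
  trFree <- simulateReplicaTraces(5, 15, meanG = c(protein = -58), seed = 27)
  est <- esmacsEstimate(tr$ensembles$complex, tr$ensembles$protein,
                        tr$ensembles$ligand, seed = 1)
  adapt <- adaptationFreeEnergy(tr$ensembles$protein,
                                trFree$ensembles$protein, seed = 1)
  total <- includeAdaptation(est, adapt)
  expect_equal(feValue(total), feValue(est) + feValue(adapt),
               tolerance = 1e-12)
  expect_true(total@adaptationIncluded)
  expect_gte(feSE(total), feSE(est))
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(n_replicas)", {
  ratios <- vapply(1:60, function(s) {
    x <- withr::with_seed(s, rnorm(24))
    bootstrapSE(x[1:6], nBoot = 400, seed = s) /
      bootstrapSE(x, nBoot = 400, seed = s + 1000)
  }, numeric(1))
  expect_equal(mean(ratios), sqrt(24 / 6), tolerance = 0.25)
})
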