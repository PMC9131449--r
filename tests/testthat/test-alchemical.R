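# Thermodynamic integration: schedule, window averages, quadrature and
# relative free-energy assembly.

test_that("default lambda schedule has the fixed 13 windows", {
  s <- defaultLambdaSchedule()
  expect_length(s, 13L)
  expect_identical(s[1], 0)
  expect_identical(s[13], 1)
  expect_true(all(diff(s) > 0))
  expect_equal(s, c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9,
                    0.95, 1))
})

test_that("window averages reduce correctly", {
  w <- windowAverage(matrix(4.2, 10, 3), seed = 1)
  expect_equal(w$mean, 4.2)
  expect_identical(w$se, 0)
  w2 <- windowAverage(cbind(rep(1, 5), rep(3, 5)), seed = 1)
  expect_equal(w2$mean, 2)
  expect_equal(unname(w2$perReplica), c(1, 3))
  expect_error(windowAverage(matrix(numeric(0), 0, 1)), "at least one")
})

test_that("window averages recover AR(1) generator truth", {
  leg <- simulateLambdaSamples(c(2, 1), noiseSd = 0.3,
                               nSamplesPerWindow = 200, nReplicas = 10,
                               seed = 31)
  lam <- lambdaSchedule(leg)
  for (w in c(1L, 7L, 13L)) {
    truthMean <- 2 + 1 * lam[w]
    wa <- windowAverage(windowSamples(leg)[[w]], seed = 1)
    expect_lt(abs(wa$mean - truthMean), 3 * max(wa$se, 1e-3))
  }
})

test_that("TI is exact on constant and linear integrands", {
  legC <- simulateLambdaSamples(7, noiseSd = 0, nSamplesPerWindow = 2,
                                nReplicas = 3, seed = 1)
  expect_equal(feValue(tiIntegrate(legC, seed = 1)), 7, tolerance = 1e-12)
  legL <- simulateLambdaSamples(c(0, 2), noiseSd = 0, nSamplesPerWindow = 2,
                                nReplicas = 3, seed = 1)
  expect_equal(feValue(tiIntegrate(legL, seed = 1)), 1, tolerance = 1e-12)
})

test_that("TI quadrature equals an independent trapezoid oracle", {
  # quadratic curve on the default schedule: the estimator must match the
  # oracle bit-for-bit and share its (small) bias against the analytic 1.0
  leg <- simulateLambdaSamples(c(0, 0, 3), noiseSd = 0,
                               nSamplesPerWindow = 1, nReplicas = 1, seed = 1)
  lam <- lambdaSchedule(leg)
  oracle <- oracleTrapz(lam, 3 * lam^2)
  expect_equal(feValue(tiIntegrate(leg, seed = 1)), oracle,
               tolerance = 1e-12)
  expect_equal(feValue(tiIntegrate(leg, seed = 1)) - 1, oracle - 1,
               tolerance = 1e-12)
  # fuzzed polynomial curves on random schedules
  withr::with_seed(32, for (i in 1:20) {
    coef <- rnorm(sample(1:4, 1), 0, 5)
    sched <- sort(c(0, 1, runif(sample(3:10, 1))))
    sched <- unique(sched)
    legF <- simulateLambdaSamples(coef, noiseSd = 0, nSamplesPerWindow = 1,
                                  nReplicas = 1, schedule = sched, seed = i)
    y <- vapply(sched, function(l)
      sum(coef * l^(seq_along(coef) - 1)), numeric(1))
    expect_equal(feValue(tiIntegrate(legF, seed = 1)),
                 oracleTrapz(sched, y), tolerance = 1e-12)
  })
})

test_that("noisy TI recovers the trapezoid-on-schedule oracle value", {
  lam <- defaultLambdaSchedule()
  oracle <- oracleTrapz(lam, 3 * lam^2)
  est <- vapply(1:20, function(s) {
    leg <- simulateLambdaSamples(c(0, 0, 3), noiseSd = 0.5,
                                 nSamplesPerWindow = 100, nReplicas = 5,
                                 seed = s)
    ti <- tiIntegrate(leg, seed = s)
    c(feValue(ti), feSE(ti))
  }, numeric(2))
  within3 <- abs(est[1, ] - oracle) <= 3 * est[2, ]
  expect_gte(sum(within3), 19L)
})

test_that("reversing the lambda axis with a sign flip negates the integral", {
  leg <- simulateLambdaSamples(c(1, -2, 4), noiseSd = 0.2,
                               nSamplesPerWindow = 20, nReplicas = 3,
                               seed = 33)
  rev_lam <- rev(1 - lambdaSchedule(leg))
  rev_samples <- rev(lapply(windowSamples(leg), function(m) -m))
  legRev <- LambdaLeg(rev_lam, rev_samples, leg = legLabel(leg),
                      pairId = pairId(leg))
  expect_equal(feValue(tiIntegrate(legRev, seed = 1)),
               -feValue(tiIntegrate(leg, seed = 1)), tolerance = 1e-12)
})

test_that("replicas missing from a window are dropped or rejected", {
  lam <- c(0, 0.5, 1)
  full <- matrix(rnorm(6), 2, dimnames = list(NULL, c("r1", "r2", "r3")))
  partial <- full[, 1:2]
  leg <- LambdaLeg(lam, list(full, partial, full))
  expect_warning(ti <- tiIntegrate(leg, seed = 1), "missing from some")
  expect_equal(nReplicas(ti), 2L)
  expect_error(suppressWarnings(tiIntegrate(leg, seed = 1, strict = TRUE)),
               "strict")
})

test_that("relative estimates assemble and guard correctly", {
  mkLeg <- function(const, leg, pid = "A->B")
    simulateLambdaSamples(const, noiseSd = 0, nSamplesPerWindow = 2,
                          nReplicas = 3, leg = leg, pairId = pid, seed = 1)
  same <- tiesEstimate(mkLeg(2, "complex"), mkLeg(2, "aqueous"), seed = 1)
  expect_equal(ddG(same), 0, tolerance = 1e-12)
  est <- tiesEstimate(mkLeg(4, "complex"), mkLeg(1.5, "aqueous"), seed = 1)
  expect_equal(ddG(est), 2.5, tolerance = 1e-12)
  expect_error(tiesEstimate(mkLeg(4, "complex"), mkLeg(1, "aqueous", "X->Y")),
               "different compound pairs")
  expect_error(tiesEstimate(mkLeg(4, "complex"), mkLeg(1, "aqueous"),
                            netCharge = c(0, 1)), "net charge")
})

test_that("swapping the legs' integrand roles negates ddG", {
  legC <- simulateLambdaSamples(c(3, 1), noiseSd = 0.1, nReplicas = 4,
                                leg = "complex", seed = 34)
  legA <- simulateLambdaSamples(c(1, 0.5), noiseSd = 0.1, nReplicas = 4,
                                leg = "aqueous", seed = 35)
  fwd <- tiesEstimate(legC, legA, seed = 1)
  swapC <- LambdaLeg(lambdaSchedule(legA), windowSamples(legA),
                     leg = "complex", pairId = pairId(legA))
  swapA <- LambdaLeg(lambdaSchedule(legC), windowSamples(legC),
                     leg = "aqueous", pairId = pairId(legC))
  bwd <- tiesEstimate(swapC, swapA, seed = 1)
  expect_equal(ddG(bwd), -ddG(fwd), tolerance = 1e-12)
})

test_that("synthetic pairs recover the constructed ddG and close cycles", {
  mk <- function(coefC, coefA, pid, seed)
    list(c = simulateLambdaSamples(coefC, noiseSd = 0.4,
                                   nSamplesPerWindow = 50, nReplicas = 5,
                                   leg = "complex", pairId = pid, seed = seed),
         a = simulateLambdaSamples(coefA, noiseSd = 0.4,
                                   nSamplesPerWindow = 50, nReplicas = 5,
                                   leg = "aqueous", pairId = pid,
                                   seed = seed + 500))
  hits <- 0L
  for (s in 1:20) {
    p <- mk(c(4), c(1.5), "A->B", s)
    est <- tiesEstimate(p$c, p$a, seed = s)
    if (abs(ddG(est) - 2.5) <= 3 * feSE(est)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # cycle A->B, B->C, A->C built so true ddGs are 2.5, 1.0, 3.5
  ab <- mk(c(4), c(1.5), "A->B", 101)
  bc <- mk(c(2), c(1), "B->C", 102)
  ac <- mk(c(6), c(2.5), "A->C", 103)
  eAB <- tiesEstimate(ab$c, ab$a, seed = 1)
  eBC <- tiesEstimate(bc$c, bc$a, seed = 2)
  eAC <- tiesEstimate(ac$c, ac$a, seed = 3)
  closure <- ddG(eAB) + ddG(eBC) - ddG(eAC)
  seClosure <- sqrt(feSE(eAB)^2 + feSE(eBC)^2 + feSE(eAC)^2)
  expect_lt(abs(closure), 3 * seClosure)
})
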