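# Potency conversion and calculation-versus-experiment statistics.

test_that("pIC50 conversion matches hand-computed values", {
  expect_identical(pic50ToDg(0), 0)
  expect_equal(pic50ToDg(6, 300), -1.9872e-3 * 300 * log(10) * 6,
               tolerance = 1e-12)
  expect_equal(pic50ToDg(6, 300), -8.236, tolerance = 1e-4)
  # one pIC50 unit at 300 K
  expect_equal(pic50ToDg(7) - pic50ToDg(6), -1.3727, tolerance = 1e-4)
})

test_that("dg -> pIC50 -> dg is the identity", {
  withr::with_seed(41, {
    dg <- runif(50, -15, -2)
    expect_equal(pic50ToDg(dgToPic50(dg)), dg, tolerance = 1e-12)
    p <- runif(50, 3, 10)
    expect_equal(dgToPic50(pic50ToDg(p, 310), 310), p, tolerance = 1e-12)
  })
})

test_that("correlations are exact on monotone constructions", {
  x <- c(1, 2, 4, 7, 11)
  r <- correlationWithCI(x, 2 * x + 1, "pearson", nBoot = 100, seed = 1)
  expect_equal(r$estimate, 1)
  expect_equal(correlationWithCI(x, 2 * x + 1, "spearman", nBoot = 100,
                                 seed = 1)$estimate, 1)
  expect_equal(correlationWithCI(x, exp(-x), "spearman", nBoot = 100,
                                 seed = 1)$estimate, -1)
  expect_error(correlationWithCI(x, rep(1, 5)), "constant")
  expect_error(correlationWithCI(x[1:3], x[1:3]), "at least 4")
})

test_that("bootstrap CI covers the population correlation", {
  rho <- 0.8
  covered <- 0L
  for (s in 1:100) {
    xy <- withr::with_seed(s, {
      x <- rnorm(20)
      cbind(x, rho * x + sqrt(1 - rho^2) * rnorm(20))
    })
    ci <- correlationWithCI(xy[, 1], xy[, 2], "pearson", nBoot = 1000,
                            seed = s)$ci
    if (ci[1] <= rho && rho <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("error metrics match a brute-force loop", {
  expect_equal(errorMetrics(c(1, 2), c(1, 2)), list(mue = 0, mse = 0))
  expect_equal(errorMetrics(c(0, 0), c(1, -1)), list(mue = 1, mse = 0))
  withr::with_seed(42, for (i in 1:20) {
    n <- sample(1:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- errorMetrics(a, b)
    want <- oracleErrorMetrics(a, b)
    expect_equal(got$mue, want$mue, tolerance = 1e-12)
    expect_equal(got$mse, want$mse, tolerance = 1e-12)
  })
  expect_error(errorMetrics(numeric(0), numeric(0)), "non-empty")
})

test_that("outlier offset orients pairs onto the named compound", {
  four <- data.frame(from = c("A", "B", "C", "D"), to = "S08",
                     ddg_calc = 1 + 3.21, ddg_exp = 1)
  expect_equal(outlierOffset("S08", four), 3.21)
  flipped <- data.frame(from = "S08", to = "A", ddg_calc = -2, ddg_exp = 0)
  expect_equal(outlierOffset("S08", flipped), 2)
  expect_error(outlierOffset("ZZZ", four), "no pair")
})

test_that("reversing every pair leaves the outlier offset unchanged", {
  withr::with_seed(43, for (i in 1:10) {
    n <- sample(2:6, 1)
    pairs <- data.frame(
      from = sample(LETTERS[1:4], n, replace = TRUE), to = "X",
      ddg_calc = rnorm(n), ddg_exp = rnorm(n))
    flipSel <- runif(n) < 0.5
    flipped <- pairs
    flipped[flipSel, c("from", "to")] <- pairs[flipSel, c("to", "from")]
    flipped$ddg_calc[flipSel] <- -pairs$ddg_calc[flipSel]
    flipped$ddg_exp[flipSel] <- -pairs$ddg_exp[flipSel]
    expect_equal(outlierOffset("X", flipped), outlierOffset("X", pairs),
                 tolerance = 1e-12)
    # brute-force oracle
    disc <- ifelse(pairs$to == "X", 1, -1) * (pairs$ddg_calc - pairs$ddg_exp)
    expect_equal(outlierOffset("X", pairs), oracleMean(disc),
                 tolerance = 1e-12)
  })
})

test_that("cross-platform agreement handles identical and constructed sets", {
  a <- data.frame(compound_id = sprintf("S%02d", 1:20),
                  value = seq(-12, -6, length.out = 20), se = 0.3)
  expect_equal(crossPlatformAgreement(a, a),
               list(meanSigned = 0, meanUnsigned = 0, fracWithin1SE = 1,
                    fracWithin2SE = 1, n = 20L))
  # 16 compounds at half a combined error bar, 4 at one and a half
  bar <- sqrt(2) * 0.3
  b <- a
  b$value <- a$value + c(rep(0.5 * bar, 16), rep(1.5 * bar, 4))
  got <- crossPlatformAgreement(a, b)
  expect_equal(got$fracWithin1SE, 0.8)
  expect_equal(got$fracWithin2SE, 1.0)
  expect_error(crossPlatformAgreement(a, a[1:10, ]), "one-to-one")
})

test_that("two noisy realizations of one truth agree within error", {
  truth <- seq(-12, -6, length.out = 15)
  mk <- function(seed) data.frame(
    compound_id = sprintf("S%02d", 1:15),
    value = truth + withr::with_seed(seed, rnorm(15, 0, 0.3)), se = 0.3)
  got <- crossPlatformAgreement(mk(1), mk(2))
  expect_lt(abs(got$meanSigned), 3 * sqrt(2) * 0.3 / sqrt(15))
})

test_that("charge stratification flags more favorable charged binding", {
  rec <- data.frame(compound_id = c("a", "b", "c", "d"),
                    net_charge = c(1L, 1L, 0L, 0L))
  est <- data.frame(compound_id = c("a", "b", "c", "d"),
                    value = c(-41, -39, -31, -29))
  got <- stratifyByCharge(rec, est)
  expect_true(got$chargedMoreFavorable)
  expect_equal(sort(got$summary$mean), c(-40, -30))
  one <- stratifyByCharge(rec[1:2, ], est[1:2, ])
  expect_identical(one$chargedMoreFavorable, NA)
  expect_equal(nrow(one$summary), 1L)
})

test_that("a constructed charged offset is recovered within noise", {
  n <- 12L
  offset <- -5
  rec <- data.frame(compound_id = sprintf("S%02d", 1:(2 * n)),
                    net_charge = rep(c(1L, 0L), each = n))
  vals <- withr::with_seed(44, {
    base <- rnorm(2 * n, -30, 1)
    base + ifelse(rec$net_charge != 0, offset, 0)
  })
  est <- data.frame(compound_id = rec$compound_id, value = vals)
  got <- stratifyByCharge(rec, est)
  diff <- got$summary$mean[got$summary$net_charge == 1] -
    got$summary$mean[got$summary$net_charge == 0]
  expect_lt(abs(diff - offset), 3 * sqrt(2 / n))
})

test_that("comparison report excludes censored compounds by default", {
  df <- simulateCompoundSet(12, expNoiseSd = 0.2, calcNoiseSd = 0.4,
                            seed = 45)
  rec <- data.frame(compound_id = df$compound_id, dg_exp = df$dg_exp,
                    censored = c(TRUE, rep(FALSE, 11)))
  est <- data.frame(compound_id = df$compound_id, value = df$dg_calc)
  rep1 <- comparisonReport(rec, est, nBoot = 200, seed = 1)
  expect_identical(rep1@excludedIds, "S01")
  expect_equal(rep1@nPairs, 11L)
  rep2 <- comparisonReport(rec, est, includeCensored = TRUE, nBoot = 200,
                           seed = 1)
  expect_equal(rep2@nPairs, 12L)
  expect_length(rep2@excludedIds, 0L)
  # CI brackets the point estimate, coefficients in range (validity)
  expect_true(rep1@pearsonCI[1] <= rep1@pearson &&
                rep1@pearson <= rep1@pearsonCI[2])
})

test_that("comparison report converts pIC50 records on the fly", {
  df <- simulateCompoundSet(10, expNoiseSd = 0.1, calcNoiseSd = 0.1,
                            seed = 46)
  rec <- data.frame(compound_id = df$compound_id,
                    pIC50 = dgToPic50(df$dg_exp))
  est <- data.frame(compound_id = df$compound_id, value = df$dg_calc)
  rep1 <- comparisonReport(rec, est, nBoot = 200, seed = 1)
  em <- errorMetrics(df$dg_exp, df$dg_calc)
  expect_equal(rep1@mue, em$mue, tolerance = 1e-9)
  expect_equal(rep1@mse, em$mse, tolerance = 1e-9)
})
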