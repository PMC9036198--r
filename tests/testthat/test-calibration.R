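test_that("stratified alpha agrees with naive Monte Carlo", {
  pan <- simulatePanel(30, seed = 101)
  m <- as.integer(miThreshold(pan))
  U <- floor(0.1 * nLoci(pan))
  set.seed(102)
  fp <- rbind(falsePositiveCurve(pan, "UNRELATED", m, cGrid = c(2, 5),
                                 nPerStratum = 4000),
              falsePositiveCurve(pan, "AUNT_UNCLE", m, cGrid = c(2, 5),
                                 nPerStratum = 4000))
  for (rel in c("UNRELATED", "AUNT_UNCLE")) {
    nv <- simulatePairStats(pan, rel, 2e5)
    pass <- nv$nmiss1 <= U & nv$nmiss2 <= U & nv$mi <= m
    for (cc in c(2, 5)) {
      aN <- mean(pass & nv$llr >= cc)
      seN <- sqrt(aN * (1 - aN) / 2e5)
      row <- fp[fp$relationship == rel & fp$c == cc, ]
      expect_lt(abs(row$alpha - aN),
                3 * sqrt(row$alpha_se^2 + seN^2) + 1e-9)
    }
  }
})

test_that("alpha is non-increasing in c and vanishes beyond the max LLR", {
  pan <- simulatePanel(25, seed = 103)
  m <- as.integer(miThreshold(pan))
  set.seed(104)
  fp <- falsePositiveCurve(pan, "AUNT_UNCLE", m, cGrid = 0:20,
                           nPerStratum = 1000)
  expect_true(all(diff(fp$alpha) <= 1e-12))
  # the summed per-locus maxima bound any pair's LLR
  tabs <- soloParentage:::.panelTables(pan)
  rmax <- sum(vapply(tabs, function(tb) max(tb$llr), numeric(1)))
  fpBeyond <- falsePositiveCurve(pan, "AUNT_UNCLE", m,
                                 cGrid = rmax + 1, nPerStratum = 1000)
  expect_identical(fpBeyond$alpha, 0)
})

test_that("full-sib error rates exceed unrelated error rates", {
  pan <- simulatePanel(50, seed = 105)
  m <- as.integer(miThreshold(pan))
  set.seed(106)
  au <- falsePositiveCurve(pan, "AUNT_UNCLE", m, cGrid = 10,
                           nPerStratum = 10000)
  un <- falsePositiveCurve(pan, "UNRELATED", m, cGrid = 10,
                           nPerStratum = 10000)
  expect_gt(au$alpha, un$alpha)
})

test_that("stratification reduces Monte Carlo variance for rare events", {
  pan <- simulatePanel(30, seed = 107)
  m <- as.integer(miThreshold(pan))
  set.seed(108)
  ns <- 4000 * (m + 1)   # equal total simulation effort
  fp <- falsePositiveCurve(pan, "UNRELATED", m, cGrid = 10,
                           nPerStratum = 4000)
  nv <- simulatePairStats(pan, "UNRELATED", ns)
  U <- floor(0.1 * nLoci(pan))
  aN <- mean(nv$nmiss1 <= U & nv$nmiss2 <= U & nv$mi <= m & nv$llr >= 10)
  seN <- sqrt(max(aN, 1 / ns) * (1 - aN) / ns)
  expect_lt(fp$alpha_se, seN)
})

test_that("false-negative curve matches enumeration on one locus", {
  p <- c(0.3, 0.7)
  pan <- SnpPanel("l", freqs = list(p), epsilon = 0.02, missRate = 0)
  set.seed(109)
  fn <- falseNegativeCurve(pan, m = 0, cGrid = c(-1, 0, 0.4), nSim = 50000)
  # exact: enumerate the 9 observed pairs of a true PO pair
  O <- observedPairDistribution(pan, 1, "PARENT_OFFSPRING")
  mi <- soloParentage:::.miMask(2)
  llr <- log(O) - log(observedPairDistribution(pan, 1, "UNRELATED"))
  for (i in seq_len(3)) {
    cc <- c(-1, 0, 0.4)[i]
    exact <- sum(O[mi | llr < cc])
    se <- sqrt(exact * (1 - exact) / 50000)
    expect_lt(abs(fn$fnr[i] - exact), 3 * se + 1e-9)
  }
})

test_that("false-negative curve is zero when every true pair passes", {
  pan <- simulatePanel(15, epsilon = 0, missSampler = function(n) rep(0, n),
                       seed = 110)
  fn <- falseNegativeCurve(pan, m = 15, cGrid = -1e9, nSim = 1000)
  expect_identical(fn$fnr, 0)
})

test_that("false-negative rates are non-decreasing along the grid", {
  pan <- simulatePanel(30, seed = 111)
  set.seed(112)
  fn <- falseNegativeCurve(pan, m = as.integer(miThreshold(pan)),
                           cGrid = 0:20, nSim = 2000)
  expect_true(all(diff(fn$fnr) >= 0))
})

test_that("false-negative missingness honours the per-individual cap", {
  pan <- simulatePanel(20, missSampler = function(n) rep(0.2, n), seed = 113)
  set.seed(114)
  pat <- soloParentage:::.sampleMissingPatterns(pan, 5000, U = 2)
  cnt <- rowSums(pat)
  expect_true(all(cnt <= 2))
  # distribution of counts matches the truncated Poisson-binomial
  d <- missingCountDistribution(pan, maxMissFrac = 0.1)
  exp0 <- unname(d$probs[1] / sum(d$probs[1:3]))
  expect_lt(abs(mean(cnt == 0) - exp0),
            3 * sqrt(exp0 * (1 - exp0) / 5000))
  # and lands on high-missing-rate loci more often
  pan2 <- SnpPanel(c("a", "b"), missRate = c(0.05, 0.3))
  pat2 <- soloParentage:::.sampleMissingPatterns(pan2, 5000, U = 1)
  expect_gt(sum(pat2[, 2]), sum(pat2[, 1]))
})

test_that("Pfs follows the full-sib family-size formula", {
  expect_identical(pfsEstimate(rep(1, 30), 30), 0)
  expect_equal(pfsEstimate(rep(2, 50), 100), 0.02)
  expect_error(pfsEstimate(integer(0), 10), "empty")
  # pedigree-counting check: fraction of aunt/uncle comparisons in a
  # simulated candidate set matches the formula
  set.seed(115)
  nFam <- 60
  sizes <- sample(1:3, nFam, replace = TRUE)
  parentFam <- rep(seq_len(nFam), sizes)
  Np <- length(parentFam)
  # each offspring has a dam and a sire drawn uniformly; a comparison with a
  # candidate is aunt/uncle iff it is a sibling of either true parent
  dams <- sample(Np, 5000, replace = TRUE)
  sires <- sample(Np, 5000, replace = TRUE)
  nAunt <- vapply(seq_len(5000), function(i)
    sum(parentFam == parentFam[dams[i]]) - 1L +
    sum(parentFam == parentFam[sires[i]]) - 1L, integer(1))
  empirical <- mean(nAunt) / Np
  # the family-size input is per candidate individual, so its plain mean is
  # the individual-weighted mean an offspring's parents see
  pfs <- pfsEstimate(sizes[parentFam], Np)
  expect_lt(abs(empirical - pfs), 3 * sd(nAunt / Np) / sqrt(5000) + 1e-9)
})

test_that("experiment-wide false-positive formulas are exact products", {
  expect_equal(round(experimentWideFP(346, 1852, 0.00087, 0.0095), 1), 5.3)
  expect_equal(round(experimentWideFP(2071, 1040, 0.00115, 0.0026), 1), 6.4)
  expect_identical(experimentWideFP(0, 1040, 0.00115, 0.0026), 0)
  expect_equal(comprehensiveFP(1e6, 0, 0.01, 0, 0, 0, 1e-3, 0, 0), 10)
  expect_identical(comprehensiveFP(100, .1, .2, .3, .4, 0, 0, 0, 0), 0)
  # reduces to the simple form when only the aunt term is non-zero
  expect_equal(comprehensiveFP(346 * 1852, 0, 0.0095, 0, 0,
                               0, 0.00087, 0, 0),
               experimentWideFP(346, 1852, 0.00087, 0.0095))
  expect_warning(comprehensiveFP(10, .5, .6, 0, 0, 0, 0, 0, 0), "sum")
})

test_that("threshold selection returns the budget crossing", {
  curve <- data.frame(c = 0:5, relationship = "AUNT_UNCLE",
                      alpha = c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002),
                      alpha_se = 0)
  fnr <- data.frame(c = 0:5, fnr = seq(0, 0.5, 0.1), fnr_se = 0)
  # budget infinite: smallest grid value
  expect_equal(selectThreshold(curve, 10, 10, 0.5, Inf)$c, 0)
  # budget between implied Fp values: unique crossing
  sel <- selectThreshold(curve, 100, 100, 0.01, 2, fnr)
  expect_equal(sel$c, 2)
  expect_lte(sel$Fp, 2)
  expect_gt(100 * 100 * curve$alpha[2] * 0.01, 2)
  expect_equal(sel$fnr, 0.2)
  expect_error(selectThreshold(curve, 1e6, 1e6, 1, 0.1), "no threshold")
})

test_that("alpha at the grid floor equals the total accepted mass", {
  pan <- simulatePanel(20, seed = 116)
  m <- as.integer(miThreshold(pan))
  set.seed(117)
  strat <- stratumSizes(pan, "AUNT_UNCLE", m, keepSlices = TRUE)
  fp <- falsePositiveCurve(pan, "AUNT_UNCLE", m, cGrid = -1e9,
                           nPerStratum = 1000, strat = strat)
  expect_equal(fp$alpha, sum(strataSizes(strat)), tolerance = 1e-10)
})
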