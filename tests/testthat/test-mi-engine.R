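test_that("per-locus event probabilities follow the missing/MI structure", {
  panNoMiss <- SnpPanel("l", freqs = list(c(0.5, 0.5)), epsilon = 0,
                        missRate = 0)
  e <- perLocusEventProbs(panNoMiss, 1, "UNRELATED")
  expect_equal(unname(e[c("cand_missing", "off_missing", "both_missing")]),
               c(0, 0, 0))
  # two unrelated individuals, p = 0.5, eps = 0: opposing homozygotes in
  # either ordering: 2 * 0.25 * 0.25
  expect_equal(unname(e["obs_MI"]), 0.125)
  expect_equal(unname(
    perLocusEventProbs(panNoMiss, 1, "PARENT_OFFSPRING")["obs_MI"]), 0)
  pan <- tinyPanel(1)
  for (rel in relationshipNames())
    expect_equal(sum(perLocusEventProbs(pan, 1, rel)), 1, tolerance = 1e-12)
})

test_that("MI threshold is 0 without error and matches the binomial tail", {
  pan0 <- simulatePanel(40, epsilon = 0, seed = 1)
  expect_identical(as.integer(miThreshold(pan0)), 0L)
  # 100 identical loci: the MI count of a true pair is Binomial(100, q)
  pan <- SnpPanel(paste0("l", 1:100), freqs = list(c(0.5, 0.5)),
                  epsilon = 0.005, missRate = 0)
  q <- unname(perLocusEventProbs(pan, 1, "PARENT_OFFSPRING")["obs_MI"])
  mOracle <- which(pbinom(0:100, 100, q) > 1 - 1e-4)[1] - 1L
  expect_identical(as.integer(miThreshold(pan, 1e-4)), mOracle)
  expect_lt(attr(miThreshold(pan), "exclusionProb"), 1e-4)
})

test_that("MI threshold is non-decreasing in the error rate", {
  base <- simulatePanel(200, seed = 8)
  ms <- vapply(c(0.001, 0.005, 0.02), function(e) {
    errorRate(base) <- e
    as.integer(miThreshold(base))
  }, integer(1))
  expect_true(all(diff(ms) >= 0))
})

test_that("missing-count distribution is the Poisson-binomial over loci", {
  pan0 <- SnpPanel(paste0("l", 1:5), missRate = 0)
  d0 <- missingCountDistribution(pan0)
  expect_equal(unname(d0$probs[1]), 1)
  expect_equal(d0$pPass, 1)
  pan <- SnpPanel(paste0("l", 1:3), missRate = c(0.1, 0.2, 0.3))
  d <- missingCountDistribution(pan, maxMissFrac = 1)
  expect_equal(unname(d$probs["0"]), 0.9 * 0.8 * 0.7)
  expect_equal(sum(d$probs), 1, tolerance = 1e-10)
  # empirical check
  set.seed(2)
  n <- 1e5
  cnt <- (runif(n) < 0.1) + (runif(n) < 0.2) + (runif(n) < 0.3)
  for (k in 0:3) {
    pk <- unname(d$probs[k + 1])
    se <- sqrt(pk * (1 - pk) / n)
    expect_lt(abs(mean(cnt == k) - pk), 3 * se + 1e-12)
  }
})

test_that("stratum sizes match exhaustive enumeration on tiny panels", {
  # 2 loci with missing data, all five relationships
  pan <- tinyPanel(2, p = c(0.3, 0.6), eps = 0.02, miss = 0.3)
  for (rel in c("UNRELATED", "PARENT_OFFSPRING", "AUNT_UNCLE")) {
    sd <- stratumSizes(pan, rel, m = 1, maxMissFrac = 0.5)
    or <- oracleStratumSizes(pan, rel, m = 1, maxMissFrac = 0.5)
    expect_equal(unname(strataSizes(sd)), or$p, tolerance = 1e-10)
    expect_equal(excludedMass(sd), or$excluded, tolerance = 1e-10)
  }
  # 3 loci, no missing
  pan3 <- tinyPanel(3, eps = 0.05, miss = 0)
  sd3 <- stratumSizes(pan3, "UNRELATED", m = 2, maxMissFrac = 0.1)
  or3 <- oracleStratumSizes(pan3, "UNRELATED", m = 2, maxMissFrac = 0.1)
  expect_equal(unname(strataSizes(sd3)), or3$p, tolerance = 1e-10)
})

test_that("stratum sizes conserve probability and respect edge cases", {
  pan <- simulatePanel(30, seed = 3)
  sd <- stratumSizes(pan, "AUNT_UNCLE", m = 3)
  expect_true(all(strataSizes(sd) >= 0))
  expect_equal(sum(strataSizes(sd)) + excludedMass(sd), 1,
               tolerance = 1e-10)
  # no missing data: excluded mass is exactly P(MI count > m)
  panNM <- simulatePanel(20, missSampler = function(n) rep(0, n), seed = 5)
  m <- 2
  sdNM <- stratumSizes(panNM, "UNRELATED", m)
  tabs <- soloParentage:::.panelTables(panNM)
  q <- vapply(tabs, function(tb) sum(tb$O[["UNRELATED"]][tb$mi]), numeric(1))
  tailP <- 1 - sum(soloParentage:::.poisbinDP(q)[seq_len(m + 1)])
  expect_equal(excludedMass(sdNM), tailP, tolerance = 1e-10)
  # eps = 0 and PO: all mass in stratum 0
  pan0 <- simulatePanel(25, epsilon = 0, missSampler = function(n) rep(0, n),
                        seed = 6)
  sd0 <- stratumSizes(pan0, "PARENT_OFFSPRING", m = 2)
  expect_equal(unname(strataSizes(sd0)), c(1, 0, 0), tolerance = 1e-12)
  expect_error(stratumSizes(pan, "UNRELATED", m = 31), "0..L")
})

test_that("stratum sizes are invariant to locus order", {
  pan <- tinyPanel(3, p = c(0.2, 0.4, 0.45), eps = 0.02, miss = 0.1)
  perm <- c(3, 1, 2)
  panPerm <- SnpPanel(lociIds(pan)[perm],
                      freqs = alleleFreqs(pan)[perm],
                      epsilon = errorRate(pan)[perm],
                      missRate = missingRate(pan)[perm])
  s1 <- stratumSizes(pan, "AUNT_UNCLE", 2, maxMissFrac = 0.5)
  s2 <- stratumSizes(panPerm, "AUNT_UNCLE", 2, maxMissFrac = 0.5)
  expect_equal(strataSizes(s1), strataSizes(s2), tolerance = 1e-12)
})

test_that("backward-sampled pairs satisfy the stratum constraints", {
  pan <- simulatePanel(25, seed = 9)
  m <- 3
  crit <- assignmentCriteria(m)
  set.seed(21)
  s <- samplePairsInStratum(pan, "UNRELATED", 2, 400, crit,
                            returnGenotypes = TRUE)
  mis <- vapply(seq_len(400), function(i)
    countMIs(genotypeVector(s$candidate, i), genotypeVector(s$offspring, i),
             pan), integer(1))
  expect_true(all(mis == 2L))
  U <- floor(0.1 * 25)
  expect_true(all(s$u1 <= U & s$u2 <= U))
  expect_equal(unname(rowSums(is.na(s$candidate@a1))), s$u1)
  expect_equal(unname(rowSums(is.na(s$offspring@a1))), s$u2)
  # PO pairs without error in stratum 0 share an allele at every locus
  pan0 <- simulatePanel(10, epsilon = 0, missSampler = function(n) rep(0, n),
                        seed = 2)
  s0 <- samplePairsInStratum(pan0, "PARENT_OFFSPRING", 0, 100,
                             assignmentCriteria(0), returnGenotypes = TRUE)
  mis0 <- vapply(seq_len(100), function(i)
    countMIs(genotypeVector(s0$candidate, i),
             genotypeVector(s0$offspring, i), pan0), integer(1))
  expect_true(all(mis0 == 0L))
  expect_error(samplePairsInStratum(pan0, "PARENT_OFFSPRING", 2, 10,
                                    assignmentCriteria(2)), "empty stratum")
})

test_that("within-stratum genotype vectors match exact conditionals", {
  # 3-locus no-missing panel: compare the sampled joint distribution of
  # ordered observed pair indices with exhaustive enumeration
  pan <- tinyPanel(3, p = c(0.25, 0.5, 0.4), eps = 0.03, miss = 0)
  j <- 1
  exact <- oraclePairVectorDist(pan, "UNRELATED", j)
  set.seed(33)
  n <- 1e5
  s <- samplePairsInStratum(pan, "UNRELATED", j, n,
                            assignmentCriteria(2, maxMissFrac = 0),
                            returnGenotypes = TRUE)
  gc1 <- soloParentage:::.genoIdxMatrix(s$candidate, pan)
  gc2 <- soloParentage:::.genoIdxMatrix(s$offspring, pan)
  pairIdx <- (gc2 - 1L) * 3L + gc1   # ordered pair index per locus, G = 3
  key <- apply(pairIdx, 1, paste, collapse = "-")
  exKey <- apply(exact$combos, 1, function(r) paste(r, collapse = "-"))
  obs <- table(factor(key, levels = exKey))
  expect_gt(suppressWarnings(
    chisq.test(as.vector(obs), p = exact$pr)$p.value), 0.001)
})

test_that("stratum-weighted conditionals reconstruct the unconditional law", {
  # single locus: p_j-weighted conditional pair distributions must equal the
  # unconditional observed-pair distribution
  pan <- tinyPanel(1, p = 0.35, eps = 0.04, miss = 0)
  sd <- stratumSizes(pan, "UNRELATED", m = 1, maxMissFrac = 0)
  O <- observedPairDistribution(pan, 1, "UNRELATED")
  mi <- soloParentage:::.miMask(2)
  condNo <- O * (!mi) / sum(O * (!mi))
  condYes <- O * mi / sum(O * mi)
  p <- strataSizes(sd)
  expect_equal(unname(p[1]) * condNo + unname(p[2]) * condYes, O,
               tolerance = 1e-10)
})
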