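test_that("MI counting follows the shared-allele rule and skips missing", {
  pan <- tinyPanel(4, p = c(0.3, 0.4, 0.5, 0.2), miss = 0)
  cand <- cbind(c(1L, 1L, 1L, NA), c(1L, 2L, 1L, NA))
  off <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L))
  # locus 1 identical, locus 2 identical het, locus 3 opposing homs,
  # locus 4 candidate missing at opposing homs
  expect_identical(countMIs(cand, off, pan), 1L)
  expect_identical(countMIs(cand, cand, pan), 0L)
  # AA vs AB does not count
  expect_identical(countMIs(cbind(1L, 1L), cbind(1L, 2L), tinyPanel(1)), 0L)
  expect_error(countMIs(cand[1:2, ], off, pan), "one row per panel locus")
})

test_that("single-locus LLR matches the closed form and the brute force", {
  # eps = 0, both observed A/A, freq(A) = p: llr = ln(1/p)
  for (p in c(0.5, 0.2)) {
    pan <- SnpPanel("l", freqs = list(c(p, 1 - p)), epsilon = 0,
                    missRate = 0)
    expect_equal(pairLLR(cbind(1L, 1L), cbind(1L, 1L), pan), log(1 / p),
                 tolerance = 1e-12)
  }
  # full marginalisation at eps = 0.005 against the brute-force double sum
  p <- c(0.3, 0.7)
  pan <- SnpPanel("l", freqs = list(p), epsilon = 0.005)
  geno <- list(cbind(1L, 1L), cbind(1L, 2L), cbind(2L, 2L))
  for (i in 1:3) for (j in 1:3)
    expect_equal(pairLLR(geno[[i]], geno[[j]], pan),
                 oracleLocusLLR(p, 0.005, i, j), tolerance = 1e-10)
})

test_that("LLR is additive over loci and zero when calls are missing", {
  pan <- tinyPanel(3, p = c(0.2, 0.45, 0.35), eps = 0.01)
  cand <- cbind(c(1L, 1L, 2L), c(2L, 1L, 2L))
  off <- cbind(c(1L, 2L, 2L), c(1L, 2L, 2L))
  total <- pairLLR(cand, off, pan)
  parts <- vapply(1:3, function(l) {
    single <- SnpPanel(lociIds(pan)[l], freqs = alleleFreqs(pan)[l],
                       epsilon = errorRate(pan)[l],
                       missRate = missingRate(pan)[l])
    pairLLR(cand[l, , drop = FALSE], off[l, , drop = FALSE], single)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-12)
  allMiss <- matrix(NA_integer_, 3, 2)
  expect_identical(pairLLR(cand, allMiss, pan), 0)
  # determinism: bit-identical on repeat
  expect_identical(pairLLR(cand, off, pan), total)
})

test_that("true PO pairs have positive expected LLR per locus", {
  pan <- simulatePanel(20, seed = 14)
  stats <- simulatePairStats(pan, "PARENT_OFFSPRING", 10000, seed = 15)
  expect_gt(mean(stats$llr), 0)
})

test_that("two-step assignment accepts the true parent and filters MIs", {
  pan <- simulatePanel(40, epsilon = 0, missSampler = function(n) rep(0, n),
                       seed = 20)
  set.seed(20)
  pairs <- simulateRelativePairs(pan, "PARENT_OFFSPRING", 5)
  cand <- pairs$candidate
  off <- pairs$offspring
  crit <- assignmentCriteria(m = 0, c = 0)
  res <- assignSingleParents(cand, off, pan, crit)
  acc <- res[res$accepted, ]
  # each offspring i was simulated from candidate i
  expect_true(all(paste0("cand", sprintf("%05d", 1:5)) %in%
                  acc$candidate_id[match(paste0("off", sprintf("%05d", 1:5)),
                                         acc$offspring_id)]))
  expect_true(all(acc$mi_count == 0))
  # candidate with m + 1 MIs injected is never accepted
  a1 <- cand@a1; a2 <- cand@a2
  o1 <- genotypeVector(off, 1)
  hom <- which(o1[, 1] == o1[, 2])[1]
  a1[1, hom] <- 3L - o1[hom, 1]; a2[1, hom] <- 3L - o1[hom, 1]
  broken <- GenotypeTable(a1, a2, individuals = individualIds(cand),
                          pop = "x", lociIds = pan)
  res2 <- assignSingleParents(broken, off[1], pan, crit)
  expect_false(individualIds(cand)[1] %in%
               res2$candidate_id[res2$offspring_id == "off00001"])
})

test_that("QC exclusion and multiple-assignment flagging behave", {
  pan <- simulatePanel(20, epsilon = 0, missSampler = function(n) rep(0, n),
                       seed = 31)
  set.seed(31)
  pairs <- simulateRelativePairs(pan, "PARENT_OFFSPRING", 3)
  # duplicate the true parent: two identical candidates both accept
  cand2 <- GenotypeTable(rbind(pairs$candidate@a1, pairs$candidate@a1[1, ]),
                         rbind(pairs$candidate@a2, pairs$candidate@a2[1, ]),
                         individuals = c(individualIds(pairs$candidate),
                                         "dup"),
                         pop = "parents", lociIds = pan)
  res <- assignSingleParents(cand2, pairs$offspring, pan,
                             assignmentCriteria(0, 0))
  acc <- res[res$accepted & res$offspring_id == "off00001", ]
  expect_setequal(acc$candidate_id, c("cand00001", "dup"))
  expect_true(all(acc$multiple_flag))
  # a sample over the missing cap is excluded up front
  a1 <- pairs$offspring@a1; a1[2, 1:10] <- NA_integer_
  a2 <- pairs$offspring@a2; a2[2, 1:10] <- NA_integer_
  offMiss <- GenotypeTable(a1, a2, individuals = individualIds(pairs$offspring),
                           pop = "offspring", lociIds = pan)
  expect_message(
    res3 <- assignSingleParents(cand2, offMiss, pan,
                                assignmentCriteria(0, 0, maxMissFrac = 0.1)),
    "excluded")
  expect_false("off00002" %in% res3$offspring_id)
  expect_identical(attr(res3, "nOffspring"), 2L)
  expect_warning(
    assignSingleParents(cand2[0], pairs$offspring, pan,
                        assignmentCriteria(0, 0)),
    "no QC-passing")
})

test_that("paired assignment recovers released pairs and respects sexes", {
  pan <- simulatePanel(60, epsilon = 0, missSampler = function(n) rep(0, n),
                       seed = 40)
  set.seed(40)
  dam <- soloParentage:::.hweMatrices(pan, 3)
  sire <- soloParentage:::.hweMatrices(pan, 3)
  kid <- soloParentage:::.mendelChildren(dam, sire)
  cand <- GenotypeTable(rbind(dam$a1, sire$a1), rbind(dam$a2, sire$a2),
                        individuals = c(paste0("D", 1:3), paste0("S", 1:3)),
                        pop = "parents", lociIds = pan)
  off <- GenotypeTable(kid$a1, kid$a2, individuals = paste0("K", 1:3),
                       pop = "offspring", lociIds = pan)
  sex <- setNames(rep(c("F", "M"), each = 3), individualIds(cand))
  crit <- assignmentCriteria(0, 0)
  pp <- assignParentPairs(cand, off, pan, crit, sex)
  expect_identical(pp$dam_id[match(paste0("K", 1:3), pp$offspring_id)],
                   paste0("D", 1:3))
  expect_identical(pp$sire_id[match(paste0("K", 1:3), pp$offspring_id)],
                   paste0("S", 1:3))
  # swapping the sex labels swaps the role columns, not the acceptance
  sexSwap <- setNames(rep(c("M", "F"), each = 3), individualIds(cand))
  pp2 <- assignParentPairs(cand, off, pan, crit, sexSwap)
  expect_identical(pp2$sire_id[match(paste0("K", 1:3), pp2$offspring_id)],
                   paste0("D", 1:3))
  # offspring of one sampled and one unsampled parent: no pair, single stays
  lone <- soloParentage:::.mendelChildren(dam, soloParentage:::.hweMatrices(pan, 3))
  offLone <- GenotypeTable(lone$a1, lone$a2, individuals = paste0("L", 1:3),
                           pop = "offspring", lociIds = pan)
  single <- assignSingleParents(cand, offLone, pan, crit)
  ppLone <- assignParentPairs(cand, offLone, pan, crit, sex, single = single)
  expect_identical(nrow(ppLone), 0L)
  expect_true(all(paste0("L", 1:3) %in%
                  single$offspring_id[single$accepted]))
})

test_that("trio threshold bounds the exclusion of true trios", {
  pan <- simulatePanel(120, seed = 55)
  mT <- trioMIThreshold(pan)
  expect_lt(attr(mT, "exclusionProb"), 1e-4)
  # empirical check: simulated true trios rarely exceed the cap
  set.seed(56)
  n <- 400
  dam <- soloParentage:::.hweMatrices(pan, n)
  sire <- soloParentage:::.hweMatrices(pan, n)
  kid <- soloParentage:::.mendelChildren(dam, sire)
  noMiss <- pan; missingRate(noMiss) <- 0
  mk <- function(g, pre) corruptGenotypes(
    GenotypeTable(g$a1, g$a2, individuals = paste0(pre, 1:n), pop = "x",
                  lociIds = pan), noMiss)
  damO <- mk(dam, "d"); sireO <- mk(sire, "s"); kidO <- mk(kid, "k")
  tm <- vapply(seq_len(n), function(i)
    soloParentage:::.trioMIcount(genotypeVector(damO, i),
                                 genotypeVector(sireO, i),
                                 genotypeVector(kidO, i)), numeric(1))
  expect_lte(mean(tm > mT), 0.01)
})
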