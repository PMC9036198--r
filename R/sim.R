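#' @include panel-model.R
NULL

#' Simulate a biallelic SNP panel
#'
#' Draws a panel of biallelic loci with minor-allele frequencies from
#' \code{freqSampler} (default uniform on 0.05-0.5, the shape of a
#' moderately informative amplicon panel), a common per-allele genotyping
#' error rate, and per-locus missing-call rates from \code{missSampler}
#' (default uniform on 0.01-0.03, mean 2\%).
#'
#' @param L number of loci (default 350).
#' @param freqSampler function(n) returning n minor-allele frequencies.
#' @param epsilon per-allele genotyping error rate (default 0.005).
#' @param missSampler function(n) returning n per-locus missing rates.
#' @param seed optional integer seed for reproducibility.
#' @return A [SnpPanel-class].
#' @export
simulatePanel <- function(L = 350,
                          freqSampler = function(n) stats::runif(n, 0.05, 0.5),
                          epsilon = 0.005,
                          missSampler = function(n) stats::runif(n, 0.01, 0.03),
                          seed = NULL) {
  stopifnot(L >= 1)
  if (!is.null(seed)) set.seed(seed)
  maf <- freqSampler(L)
  SnpPanel(sprintf("snp%04d", seq_len(L)),
           freqs = lapply(maf, function(q) c(1 - q, q)),
           epsilon = epsilon, missRate = missSampler(L))
}

## n HWE individuals as a pair of allele-index matrices (n x L)
.hweMatrices <- function(panel, n) {
  L <- nLoci(panel)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    f <- panel@freqs[[l]]
    a1[, l] <- sample.int(length(f), n, replace = TRUE, prob = f)
    a2[, l] <- sample.int(length(f), n, replace = TRUE, prob = f)
  }
  list(a1 = a1, a2 = a2)
}

## Mendelian children: row i of the output descends from row i of dam and
## row i of sire (allele-index matrices)
.mendelChildren <- function(dam, sire) {
  pickD <- matrix(stats::runif(length(dam$a1)) < 0.5, nrow(dam$a1))
  pickS <- matrix(stats::runif(length(sire$a1)) < 0.5, nrow(sire$a1))
  list(a1 = ifelse(pickD, dam$a1, dam$a2),
       a2 = ifelse(pickS, sire$a1, sire$a2))
}

#' Study scenario for the population simulator
#'
#' Bundles the release design and generative parameters of a simulated
#' spawning season: released counts by sex, unsampled resident spawners,
#' per-sex mating-strategy fractions, offspring counts per mating, full-sib
#' family structure among the released adults, and phenotype models.  The
#' two named defaults emulate the male-biased release (238 males / 108
#' females) and the near-equal release (977 males / 1094 females).
#'
#' @param name "maleBiased", "nearEqual", or "custom".
#' @param ... overrides for any scenario field (see Details).
#' @details Fields: \code{nMales}, \code{nFemales} (released counts);
#'   \code{residentMatings} (matings between two unsampled residents, whose
#'   offspring can receive no assignment); \code{strategyFractions} (list
#'   with \code{male} and \code{female} probability vectors over
#'   \code{assortative}, \code{disassortative}, \code{both});
#'   \code{offspringPerMating} (function(n) of sampled offspring counts);
#'   \code{sibStructure} (list: \code{sizes}, a probability vector over
#'   full-sib family sizes named by size, and \code{halfSibProb}, the
#'   probability a family shares a sire with the previous family);
#'   \code{phenotypes} (per sex x strategy age probabilities, mean fork
#'   length by age, and SD).
#' @return A list of class \code{"StudyScenario"}.
#' @export
studyScenario <- function(name = c("maleBiased", "nearEqual", "custom"),
                          ...) {
  name <- match.arg(name)
  maleAssort <- list(ageProbs = c("3" = 0.29, "4" = 0.52, "5" = 0.19),
                     flMean = c("3" = 439.3, "4" = 543.7, "5" = 585.0),
                     flSD = 45)
  maleDis <- list(ageProbs = c("3" = 0.93, "4" = 0.07),
                  flMean = c("3" = 391.4, "4" = 518.8), flSD = 40)
  femaleAll <- list(ageProbs = c("3" = 0.3, "4" = 0.5, "5" = 0.2),
                    flMean = c("3" = 480, "4" = 520, "5" = 560), flSD = 50)
  base <- list(
    name = name,
    nMales = 238, nFemales = 108,
    residentMatings = 150,
    strategyFractions = list(
      male = c(assortative = 0.40, disassortative = 0.50, both = 0.10),
      female = c(assortative = 0.80, disassortative = 0.10, both = 0.10)),
    offspringPerMating = function(n) stats::rpois(n, 3),
    sibStructure = list(
      sizes = c("1" = 0.85, "2" = 0.10, "3" = 0.04, "4" = 0.01),
      halfSibProb = 0.5),
    phenotypes = list(
      male = list(assortative = maleAssort, disassortative = maleDis,
                  both = maleAssort),
      female = list(assortative = femaleAll, disassortative = femaleAll,
                    both = femaleAll))
  )
  if (name == "nearEqual") {
    base$nMales <- 977; base$nFemales <- 1094
    base$residentMatings <- 250
    base$strategyFractions <- list(
      male = c(assortative = 0.94, disassortative = 0.01, both = 0.05),
      female = c(assortative = 0.78, disassortative = 0.06, both = 0.16))
    base$sibStructure <- list(
      sizes = c("1" = 0.30, "2" = 0.25, "3" = 0.20, "4" = 0.15, "6" = 0.10),
      halfSibProb = 0.3)
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  stopifnot(abs(sum(base$strategyFractions$male) - 1) < 1e-9,
            abs(sum(base$strategyFractions$female) - 1) < 1e-9,
            base$nMales >= 0, base$nFemales >= 0)
  structure(base, class = "StudyScenario")
}

#' @export
print.StudyScenario <- function(x, ...) {
  cat("StudyScenario '", x$name, "': ", x$nMales, " released males, ",
      x$nFemales, " released females, ", x$residentMatings,
      " resident-only matings\n", sep = "")
  invisible(x)
}

#' Simulate a pedigreed spawning population
#'
#' Generates true genotypes and pedigree for one spawning season: released
#' adults with full-sib/half-sib family structure (realised by drawing them
#' as offspring of virtual grandparent matings), unsampled resident
#' spawners, matings according to each parent's strategy (assortative =
#' released x released; disassortative = released x resident; "both" = one
#' of each), resident-only matings, offspring by Mendelian inheritance, and
#' phenotypes (age, fork length).  Genotypes are error-free and complete;
#' apply [corruptGenotypes()] to obtain observed calls.
#'
#' @param panel a [SnpPanel-class].
#' @param scenario a [studyScenario()].
#' @param seed optional integer seed.
#' @return A list of class \code{"SimulatedStudy"}: \code{parents} and
#'   \code{offspring} ([GenotypeTable-class] of true genotypes; parents are
#'   the released, sampled candidates), \code{truth} (per offspring: true
#'   dam/sire ids and their sampled status), \code{metadata} (per released
#'   parent: sex, planted strategy, age, fork length in mm),
#'   \code{familySizes} (each released adult's realised full-sib family
#'   size, so its plain mean is the individual-weighted mean an offspring's
#'   parents see; feed to [pfsEstimate()]), \code{matings}, and the
#'   scenario.
#' @export
simulatePopulation <- function(panel, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "StudyScenario"))
  if (!is.null(seed)) set.seed(seed)
  N <- scenario$nMales + scenario$nFemales
  ## full-sib families among released adults
  szProbs <- scenario$sibStructure$sizes
  szVals <- as.integer(names(szProbs))
  sizes <- integer(0)
  while (sum(sizes) < N)
    sizes <- c(sizes, sample(szVals, 50, replace = TRUE, prob = szProbs))
  famOf <- rep(seq_along(sizes), sizes)[seq_len(N)]
  nFam <- max(famOf)
  famSizes <- tabulate(famOf, nFam)
  ## virtual grandparents; half-sib links via shared grandsires
  sireOfFam <- integer(nFam)
  nextSire <- 0L
  for (f in seq_len(nFam)) {
    if (f > 1L && stats::runif(1) < scenario$sibStructure$halfSibProb)
      sireOfFam[f] <- sireOfFam[f - 1L]
    else {
      nextSire <- nextSire + 1L
      sireOfFam[f] <- nextSire
    }
  }
  gdam <- .hweMatrices(panel, nFam)
  gsire <- .hweMatrices(panel, nextSire)
  rel <- .mendelChildren(
    list(a1 = gdam$a1[famOf, , drop = FALSE],
         a2 = gdam$a2[famOf, , drop = FALSE]),
    list(a1 = gsire$a1[sireOfFam[famOf], , drop = FALSE],
         a2 = gsire$a2[sireOfFam[famOf], , drop = FALSE]))
  sex <- sample(rep(c("M", "F"), c(scenario$nMales, scenario$nFemales)))
  ids <- sprintf("P%04d", seq_len(N))
  strat <- character(N)
  fr <- scenario$strategyFractions
  strat[sex == "M"] <- sample(names(fr$male), sum(sex == "M"),
                              replace = TRUE, prob = fr$male)
  strat[sex == "F"] <- sample(names(fr$female), sum(sex == "F"),
                              replace = TRUE, prob = fr$female)
  ## matings
  males <- ids[sex == "M"]; females <- ids[sex == "F"]
  stratM <- strat[sex == "M"]; stratF <- strat[sex == "F"]
  offerM <- males[stratM %in% c("assortative", "both")]
  mDam <- character(0); mSire <- character(0)
  fAss <- females[stratF %in% c("assortative", "both")]
  if (length(offerM) > 0L && length(fAss) > 0L) {
    mDam <- c(mDam, fAss)
    mSire <- c(mSire, sample(offerM, length(fAss), replace = TRUE))
  }
  fDis <- females[stratF %in% c("disassortative", "both")]
  if (length(fDis) > 0L) {
    mDam <- c(mDam, fDis)
    mSire <- c(mSire, sprintf("RM%04d", seq_along(fDis)))
  }
  mDis <- males[stratM %in% c("disassortative", "both")]
  if (length(mDis) > 0L) {
    mDam <- c(mDam, sprintf("RF%04d", seq_along(mDis)))
    mSire <- c(mSire, mDis)
  }
  if (scenario$residentMatings > 0L) {
    mDam <- c(mDam, sprintf("RRF%04d", seq_len(scenario$residentMatings)))
    mSire <- c(mSire, sprintf("RRM%04d", seq_len(scenario$residentMatings)))
  }
  matings <- data.frame(dam = mDam, sire = mSire,
                        damSampled = mDam %in% ids,
                        sireSampled = mSire %in% ids)
  ## genotypes of every mating's dam and sire (residents drawn HWE)
  resIds <- unique(c(mDam[!matings$damSampled], mSire[!matings$sireSampled]))
  res <- .hweMatrices(panel, length(resIds))
  lookup <- function(who) {
    i <- match(who, ids)
    j <- match(who, resIds)
    a1 <- matrix(0L, length(who), nLoci(panel)); a2 <- a1
    a1[!is.na(i), ] <- rel$a1[i[!is.na(i)], , drop = FALSE]
    a2[!is.na(i), ] <- rel$a2[i[!is.na(i)], , drop = FALSE]
    a1[!is.na(j), ] <- res$a1[j[!is.na(j)], , drop = FALSE]
    a2[!is.na(j), ] <- res$a2[j[!is.na(j)], , drop = FALSE]
    list(a1 = a1, a2 = a2)
  }
  nOff <- scenario$offspringPerMating(nrow(matings))
  offMating <- rep(seq_len(nrow(matings)), nOff)
  damG <- lookup(matings$dam[offMating])
  sireG <- lookup(matings$sire[offMating])
  offG <- .mendelChildren(damG, sireG)
  offIds <- sprintf("O%05d", seq_along(offMating))
  truth <- data.frame(offspring = offIds,
                      dam = matings$dam[offMating],
                      sire = matings$sire[offMating],
                      damSampled = matings$damSampled[offMating],
                      sireSampled = matings$sireSampled[offMating])
  ## phenotypes for released adults
  age <- integer(N); fl <- numeric(N)
  for (i in seq_len(N)) {
    mod <- scenario$phenotypes[[if (sex[i] == "M") "male" else "female"]][[strat[i]]]
    age[i] <- as.integer(sample(names(mod$ageProbs), 1, prob = mod$ageProbs))
    fl[i] <- stats::rnorm(1, mod$flMean[[as.character(age[i])]], mod$flSD)
  }
  structure(list(
    panel = panel,
    parents = GenotypeTable(rel$a1, rel$a2, individuals = ids,
                            pop = "parents", lociIds = panel),
    offspring = GenotypeTable(offG$a1, offG$a2, individuals = offIds,
                              pop = "offspring", lociIds = panel),
    truth = truth,
    metadata = data.frame(id = ids, sex = sex, strategy = strat,
                          age = age, forkLength = fl),
    familySizes = famSizes[famOf],
    matings = matings,
    scenario = scenario
  ), class = "SimulatedStudy")
}

#' True mating-strategy categories from a simulated study
#'
#' Derives, for every released parent, the category its sampled offspring
#' imply under perfect assignment: offspring with the other parent sampled
#' give assortative evidence, offspring with the other parent unsampled give
#' disassortative evidence; parents with both kinds are "both"; parents with
#' no sampled offspring are "none".
#'
#' @param study a [simulatePopulation()] result.
#' @return data.frame with \code{id}, \code{sex}, \code{category}.
#' @export
trueStrategies <- function(study) {
  stopifnot(inherits(study, "SimulatedStudy"))
  md <- study$metadata
  tr <- study$truth
  cat <- vapply(md$id, function(id) {
    asDam <- tr$dam == id
    asSire <- tr$sire == id
    other <- c(tr$sireSampled[asDam], tr$damSampled[asSire])
    if (length(other) == 0L) return("none")
    if (all(other)) return("assortative")
    if (all(!other)) return("disassortative")
    "both"
  }, character(1))
  data.frame(id = md$id, sex = md$sex, category = unname(cat))
}

#' Apply the observation model to true genotypes
#'
#' Each allele is misread independently with probability \code{epsilon}
#' (substituting an allele drawn uniformly from the locus's other alleles)
#' and each call is set missing independently with the locus's missing rate.
#'
#' @param gt a [GenotypeTable-class] of true genotypes.
#' @param panel a [SnpPanel-class] with \code{epsilon} and \code{missRate}.
#' @param seed optional integer seed.
#' @return A [GenotypeTable-class] of observed calls.
#' @export
corruptGenotypes <- function(gt, panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nIndividuals(gt)
  a1 <- gt@a1; a2 <- gt@a2
  for (l in seq_len(nLoci(panel))) {
    k <- length(panel@alleles[[l]])
    eps <- panel@epsilon[l]
    if (eps > 0) {
      for (mat in c("a1", "a2")) {
        a <- get(mat)[, l]
        err <- stats::runif(n) < eps
        if (any(err)) {
          shift <- sample.int(k - 1L, sum(err), replace = TRUE)
          a[err] <- ifelse(shift >= a[err], shift + 1L, shift)
          if (mat == "a1") a1[, l] <- a else a2[, l] <- a
        }
      }
    }
    if (panel@missRate[l] > 0) {
      gone <- stats::runif(n) < panel@missRate[l]
      a1[gone, l] <- NA_integer_
      a2[gone, l] <- NA_integer_
    }
  }
  GenotypeTable(a1, a2, individuals = gt@individuals, pop = gt@pop,
                lociIds = gt@lociIds)
}

#' Simulate observed genotype pairs of a given relationship
#'
#' Draws candidate/offspring pairs through explicit mini-pedigrees (e.g.
#' aunt/uncle pairs via grandparents, two full siblings, and a child of one
#' sibling), then applies the observation model.  This is the naive Monte
#' Carlo counterpart of the stratified machinery and serves as its
#' independent oracle.
#'
#' @param panel a [SnpPanel-class].
#' @param rel relationship name (see [relationshipNames()]).
#' @param n number of pairs.
#' @param corrupt apply genotyping error and missingness (default TRUE).
#' @param seed optional integer seed.
#' @return List with [GenotypeTable-class] elements \code{candidate} and
#'   \code{offspring} (row i of each forms pair i).
#' @export
simulateRelativePairs <- function(panel, rel, n, corrupt = TRUE,
                                  seed = NULL) {
  rel <- match.arg(rel, relationshipNames())
  if (!is.null(seed)) set.seed(seed)
  L <- nLoci(panel)
  ca1 <- matrix(0L, n, L); ca2 <- ca1; oa1 <- ca1; oa2 <- ca1
  pick <- function(a, b) ifelse(stats::runif(n) < 0.5, a, b)
  for (l in seq_len(L)) {
    f <- panel@freqs[[l]]
    dr <- function() sample.int(length(f), n, replace = TRUE, prob = f)
    if (rel == "UNRELATED") {
      c1 <- dr(); c2 <- dr(); o1 <- dr(); o2 <- dr()
    } else if (rel == "PARENT_OFFSPRING") {
      c1 <- dr(); c2 <- dr(); o1 <- pick(c1, c2); o2 <- dr()
    } else if (rel == "AUNT_UNCLE") {
      g1a <- dr(); g1b <- dr(); g2a <- dr(); g2b <- dr()
      s1a <- pick(g1a, g1b); s1b <- pick(g2a, g2b)
      c1 <- pick(g1a, g1b); c2 <- pick(g2a, g2b)
      o1 <- pick(s1a, s1b); o2 <- dr()
    } else if (rel == "HALF_AUNT_UNCLE") {
      sa <- dr(); sb <- dr()
      h1a <- pick(sa, sb); h1b <- dr()
      c1 <- pick(sa, sb); c2 <- dr()
      o1 <- pick(h1a, h1b); o2 <- dr()
    } else {  # COUSIN_OF_PARENT
      g1a <- dr(); g1b <- dr(); g2a <- dr(); g2b <- dr()
      sAa <- pick(g1a, g1b); sAb <- pick(g2a, g2b)
      sBa <- pick(g1a, g1b); sBb <- pick(g2a, g2b)
      pa <- pick(sAa, sAb); pb <- dr()
      c1 <- pick(sBa, sBb); c2 <- dr()
      o1 <- pick(pa, pb); o2 <- dr()
    }
    ca1[, l] <- c1; ca2[, l] <- c2; oa1[, l] <- o1; oa2[, l] <- o2
  }
  cand <- GenotypeTable(ca1, ca2, individuals = sprintf("cand%05d", 1:n),
                        pop = "sim_candidate", lociIds = panel)
  off <- GenotypeTable(oa1, oa2, individuals = sprintf("off%05d", 1:n),
                       pop = "sim_offspring", lociIds = panel)
  if (corrupt) {
    cand <- corruptGenotypes(cand, panel)
    off <- corruptGenotypes(off, panel)
  }
  list(candidate = cand, offspring = off)
}

#' Fast per-pair summaries for simulated relative pairs
#'
#' Simulates \code{n} observed pairs of the given relationship (same
#' allele-level pedigree model as [simulateRelativePairs()], implemented in
#' C++ for large \code{n}) and returns, per pair, the observed MI count, the
#' summed LLR over loci with both calls observed, and each individual's
#' missing-call count.  Used as the naive Monte Carlo estimator of false
#' positive/negative rates.
#'
#' @inheritParams simulateRelativePairs
#' @param applyMissing draw missing calls (default TRUE).
#' @return data.frame with columns \code{mi}, \code{llr}, \code{nmiss1}
#'   (candidate), \code{nmiss2} (offspring).
#' @export
simulatePairStats <- function(panel, rel, n, applyMissing = TRUE,
                              seed = NULL) {
  rel <- match.arg(rel, relationshipNames())
  if (!is.null(seed)) set.seed(seed)
  relCode <- c(UNRELATED = 0L, PARENT_OFFSPRING = 1L, AUNT_UNCLE = 2L,
               HALF_AUNT_UNCLE = 3L, COUSIN_OF_PARENT = 4L)[[rel]]
  tables <- .panelTables(panel, c("PARENT_OFFSPRING", "UNRELATED"))
  cpp_pair_stats(lapply(panel@freqs, cumsum), panel@epsilon, panel@missRate,
                 relCode, lapply(tables, `[[`, "llr"), as.integer(n),
                 isTRUE(applyMissing))
}
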