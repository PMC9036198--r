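#' @include AllClasses.R
NULL

## Relationship categories, parameterised by IBD-sharing coefficients
## (k0, k1, k2) under the assumption of no inbreeding and unlinked loci.
.REL_IBD <- list(
  PARENT_OFFSPRING = c(k0 = 0,     k1 = 1,    k2 = 0),
  UNRELATED        = c(k0 = 1,     k1 = 0,    k2 = 0),
  AUNT_UNCLE       = c(k0 = 1 / 2, k1 = 1 / 2, k2 = 0),
  HALF_AUNT_UNCLE  = c(k0 = 3 / 4, k1 = 1 / 4, k2 = 0),
  COUSIN_OF_PARENT = c(k0 = 7 / 8, k1 = 1 / 8, k2 = 0)
)

#' Supported relationship categories
#'
#' The candidate-vs-offspring relationships for which error rates are
#' computed: true parent, unrelated, and the three classes of close relative
#' of the true parent (its full sibling, half sibling and first cousin, i.e.
#' aunt/uncle, half-aunt/uncle and cousin-of-parent of the offspring).
#'
#' @return Character vector of relationship names.
#' @examples
#' relationshipNames()
#' ibdCoefficients("AUNT_UNCLE")
#' @export
relationshipNames <- function() names(.REL_IBD)

#' IBD-sharing coefficients of a relationship
#'
#' @param rel relationship name, one of [relationshipNames()].
#' @return Numeric vector \code{c(k0, k1, k2)}: probabilities that the pair
#'   shares 0, 1 or 2 alleles identical by descent at a locus.
#' @export
ibdCoefficients <- function(rel) {
  rel <- match.arg(rel, names(.REL_IBD))
  .REL_IBD[[rel]]
}

## ---- genotype bookkeeping ----------------------------------------------

## unordered genotypes of a k-allele locus, enumerated (1,1),(1,2),..,(k,k)
.genoEnum <- function(k) {
  i <- rep(seq_len(k), times = k - seq_len(k) + 1L)
  j <- unlist(lapply(seq_len(k), function(a) a:k), use.names = FALSE)
  cbind(a1 = i, a2 = j)
}

## map an (a1, a2) allele pair (a1 <= a2) to its genotype index
.genoIndex <- function(a1, a2, k) {
  (a1 - 1L) * k - ((a1 - 1L) * (a1 - 2L)) %/% 2L + (a2 - a1 + 1L)
}

.genoLabels <- function(alleles) {
  g <- .genoEnum(length(alleles))
  paste0(alleles[g[, 1]], "/", alleles[g[, 2]])
}

## HWE genotype probabilities for one locus
.hweProbs <- function(p) {
  g <- .genoEnum(length(p))
  pr <- p[g[, 1]] * p[g[, 2]]
  pr[g[, 1] != g[, 2]] <- 2 * pr[g[, 1] != g[, 2]]
  pr
}

## ---- observation error model -------------------------------------------

#' Genotype observation error matrix for one locus
#'
#' Each allele of the true genotype is misread independently with probability
#' \code{epsilon}; a misread substitutes an allele drawn uniformly from the
#' other alleles of the locus (for a biallelic SNP, the unique flip model).
#' Rows are true genotypes, columns observed genotypes; rows sum to 1.
#'
#' @param panel a [SnpPanel-class].
#' @param locus locus index or id.
#' @return Square matrix \code{P(observed | true)} over unordered genotypes.
#' @examples
#' pan <- SnpPanel("s1", freqs = list(c(.3, .7)), epsilon = 0.01)
#' observationErrorMatrix(pan, 1)
#' @export
observationErrorMatrix <- function(panel, locus) {
  l <- .locusPos(panel, locus)
  E <- .errMatrix(length(panel@alleles[[l]]), panel@epsilon[l])
  dimnames(E) <- list(true = .genoLabels(panel@alleles[[l]]),
                      observed = .genoLabels(panel@alleles[[l]]))
  E
}

.errMatrix <- function(k, eps) {
  if (eps >= 0.5) stop("epsilon must be < 0.5")
  ## allele-level misread kernel
  A <- matrix(eps / (k - 1), k, k)
  diag(A) <- 1 - eps
  g <- .genoEnum(k)
  G <- nrow(g)
  E <- matrix(0, G, G)
  for (t in seq_len(G)) {
    a <- g[t, 1]; b <- g[t, 2]
    ## joint over ordered observed alleles (x from a, y from b)
    J <- outer(A[a, ], A[b, ])
    for (o in seq_len(G)) {
      x <- g[o, 1]; y <- g[o, 2]
      E[t, o] <- if (x == y) J[x, y] else J[x, y] + J[y, x]
    }
  }
  E
}

.locusPos <- function(panel, locus) {
  if (is.character(locus)) {
    l <- match(locus, panel@ids)
    if (is.na(l)) stop("unknown locus id: ", locus)
    return(l)
  }
  as.integer(locus)
}

## ---- relationship-conditional genotype-pair distributions ---------------

## joint distribution of TRUE ordered (candidate, offspring) genotypes under
## an IBD mixture: k0 independent HWE draws, k1 one allele shared IBD (shared
## allele from the frequency distribution, remaining alleles independent HWE
## draws), k2 identical genotypes.
.truePairDist <- function(p, kvec) {
  k <- length(p)
  g <- .genoEnum(k)
  G <- nrow(g)
  hwe <- .hweProbs(p)
  T0 <- outer(hwe, hwe)
  T2 <- diag(hwe, G)
  ## P(genotype g | one allele is s): the other allele ~ p
  condShared <- matrix(0, k, G)
  for (s in seq_len(k)) for (gi in seq_len(G)) {
    a <- g[gi, 1]; b <- g[gi, 2]
    if (a == s && b == s) condShared[s, gi] <- p[s]
    else if (a == s) condShared[s, gi] <- p[b]
    else if (b == s) condShared[s, gi] <- p[a]
  }
  T1 <- t(condShared) %*% (p * condShared)
  kvec[["k0"]] * T0 + kvec[["k1"]] * T1 + kvec[["k2"]] * T2
}

#' Joint distribution of observed genotype pairs under a relationship
#'
#' Probability of each ordered (candidate, offspring) pair of observed
#' unordered genotypes at one locus, conditional on both calls being
#' observed.  The true pair is drawn as a mixture over IBD states given the
#' relationship, assuming Hardy-Weinberg equilibrium and no inbreeding, and
#' the genotyping-error model is then applied independently to each member.
#'
#' @param panel a [SnpPanel-class] with frequencies and error rates set.
#' @param locus locus index or id.
#' @param rel relationship name, see [relationshipNames()].
#' @return Square matrix over observed genotypes (candidate rows, offspring
#'   columns) summing to 1.
#' @examples
#' pan <- SnpPanel("s1", freqs = list(c(.5, .5)), epsilon = 0)
#' observedPairDistribution(pan, 1, "UNRELATED")["A/A", "B/B"]  # 0.0625
#' @export
observedPairDistribution <- function(panel, locus, rel) {
  l <- .locusPos(panel, locus)
  kvec <- ibdCoefficients(rel)
  p <- panel@freqs[[l]]
  Tm <- .truePairDist(p, kvec)
  E <- .errMatrix(length(p), panel@epsilon[l])
  O <- t(E) %*% Tm %*% E
  lab <- .genoLabels(panel@alleles[[l]])
  dimnames(O) <- list(candidate = lab, offspring = lab)
  O
}

## logical matrix over ordered genotype pairs: TRUE where the two genotypes
## share no allele (the Mendelian-incompatibility event)
.miMask <- function(k) {
  g <- .genoEnum(k)
  G <- nrow(g)
  outer(seq_len(G), seq_len(G), Vectorize(function(i, j) {
    length(intersect(g[i, ], g[j, ])) == 0L
  }))
}

## per-locus tables used across the package; computed once per panel
.panelTables <- function(panel, rels = relationshipNames()) {
  lapply(seq_len(nLoci(panel)), function(l) {
    p <- panel@freqs[[l]]
    k <- length(p)
    E <- .errMatrix(k, panel@epsilon[l])
    hwe <- .hweProbs(p)
    obsMarg <- as.vector(t(E) %*% hwe)  # marginal observed genotype dist
    O <- lapply(rels, function(r)
      t(E) %*% .truePairDist(p, ibdCoefficients(r)) %*% E)
    names(O) <- rels
    mi <- .miMask(k)
    llr <- log(O[["PARENT_OFFSPRING"]]) - log(O[["UNRELATED"]])
    list(k = k, G = nrow(mi), hwe = hwe, E = E, obsMarg = obsMarg,
         O = O, mi = mi, llr = llr)
  })
}

## ---- estimation from observed genotype tables ---------------------------

#' Estimate allele frequencies from parent genotypes
#'
#' Posterior-mean allele frequencies with a Dirichlet(0.5, ..., 0.5) prior
#' (Beta(0.5, 0.5) in the biallelic case) applied to observed allele counts
#' among the candidate parents: each allele's count is incremented by 0.5 and
#' the counts normalised.
#'
#' @param parents a [GenotypeTable-class] of candidate parents.
#' @param panel a [SnpPanel-class] declaring the alleles.
#' @return The panel with the \code{freqs} slot replaced by the estimates.
#' @export
estimateAlleleFreqs <- function(parents, panel) {
  if (nIndividuals(parents) == 0L) stop("parent table is empty")
  L <- nLoci(panel)
  for (l in seq_len(L)) {
    k <- length(panel@alleles[[l]])
    if (k == 0L) stop("invalid panel: locus with no declared alleles")
    cnt <- tabulate(c(parents@a1[, l], parents@a2[, l]), nbins = k)
    post <- cnt + 0.5
    panel@freqs[[l]] <- post / sum(post)
  }
  validObject(panel)
  panel
}

#' Estimate per-locus missing-call rates
#'
#' Posterior mean with a Beta(0.5, 0.5) prior on the observed frequency of
#' missing genotype calls, pooling candidate parents and offspring:
#' \code{(n_missing + 0.5) / (n + 1)} per locus.
#'
#' @param parents,offspring [GenotypeTable-class] objects (either may be
#'   empty, but not both).
#' @param panel a [SnpPanel-class].
#' @return The panel with the \code{missRate} slot replaced by the estimates.
#' @export
estimateMissingRates <- function(parents, offspring, panel) {
  n <- nIndividuals(parents) + nIndividuals(offspring)
  if (n == 0L) stop("no individuals to estimate missing rates from")
  nmiss <- colSums(is.na(parents@a1)) + colSums(is.na(offspring@a1))
  panel@missRate <- as.numeric((nmiss + 0.5) / (n + 1))
  validObject(panel)
  panel
}
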