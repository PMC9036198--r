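#' @import methods
NULL

#' SNP panel with locus-level model parameters
#'
#' A \code{SnpPanel} holds, for each locus, the allele labels, population
#' allele frequencies, the per-allele genotyping error rate and the rate of
#' missing genotype calls.  Every downstream computation (Mendelian
#' incompatibility probabilities, likelihood ratios, stratified Monte Carlo)
#' conditions on these values, which are estimated once and then treated as
#' known.
#'
#' @slot ids character vector of unique locus identifiers.
#' @slot alleles list of character vectors (>= 2 allele labels per locus).
#' @slot freqs list of numeric vectors; each sums to 1 with all entries > 0.
#' @slot epsilon numeric vector of per-allele genotyping error rates, one per
#'   locus, each in [0, 0.5).
#' @slot missRate numeric vector of per-locus missing-call probabilities in
#'   [0, 1].
#'
#' @seealso [SnpPanel()], [simulatePanel()], [estimateAlleleFreqs()]
#' @export
setClass("SnpPanel",
  representation(
    ids = "character",
    alleles = "list",
    freqs = "list",
    epsilon = "numeric",
    missRate = "numeric"
  )
)

setValidity("SnpPanel", function(object) {
  L <- length(object@ids)
  msg <- character()
  if (anyDuplicated(object@ids))
    msg <- c(msg, "locus ids must be unique")
  if (length(object@alleles) != L || length(object@freqs) != L ||
      length(object@epsilon) != L || length(object@missRate) != L)
    msg <- c(msg, "all slots must have one entry per locus")
  for (l in seq_len(L)) {
    al <- object@alleles[[l]]
    fr <- object@freqs[[l]]
    if (length(al) < 2L)
      msg <- c(msg, sprintf("locus %s: fewer than 2 alleles", object@ids[l]))
    if (anyDuplicated(al))
      msg <- c(msg, sprintf("locus %s: duplicated allele labels", object@ids[l]))
    if (length(fr) != length(al))
      msg <- c(msg, sprintf("locus %s: freqs/alleles length mismatch", object@ids[l]))
    else if (abs(sum(fr) - 1) > 1e-12 || any(fr <= 0))
      msg <- c(msg, sprintf("locus %s: freqs must be > 0 and sum to 1", object@ids[l]))
  }
  if (any(object@epsilon < 0 | object@epsilon >= 0.5))
    msg <- c(msg, "epsilon must satisfy 0 <= epsilon < 0.5")
  if (any(object@missRate < 0 | object@missRate > 1))
    msg <- c(msg, "missRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SnpPanel
#'
#' @param ids character vector of locus ids.
#' @param alleles list of character vectors of allele labels, or a single
#'   character vector recycled to all loci (default biallelic \code{c("A","B")}).
#' @param freqs list of numeric allele-frequency vectors, or NULL for uniform
#'   frequencies at every locus.
#' @param epsilon per-allele genotyping error rate(s); scalar recycled.
#'   Default 0.005 (0.5\% per allele).
#' @param missRate per-locus missing-call rate(s); scalar recycled. Default 0.
#' @return A [SnpPanel-class] object.
#' @examples
#' pan <- SnpPanel(paste0("snp", 1:3), freqs = list(c(.3,.7), c(.5,.5), c(.1,.9)))
#' nLoci(pan)
#' @export
SnpPanel <- function(ids, alleles = c("A", "B"), freqs = NULL,
                     epsilon = 0.005, missRate = 0) {
  L <- length(ids)
  if (!is.list(alleles)) alleles <- rep(list(alleles), L)
  if (is.null(freqs))
    freqs <- lapply(alleles, function(a) rep(1 / length(a), length(a)))
  if (!is.list(freqs)) freqs <- rep(list(freqs), L)
  else if (length(freqs) == 1L && L > 1L) freqs <- rep(freqs, L)
  new("SnpPanel",
      ids = as.character(ids), alleles = alleles, freqs = freqs,
      epsilon = rep_len(as.numeric(epsilon), L),
      missRate = rep_len(as.numeric(missRate), L))
}

#' Observed genotype calls for a set of individuals
#'
#' Unordered allele-pair calls (or missing) for individuals x loci.  Alleles
#' are stored as integer indices into the corresponding locus's allele vector
#' of a [SnpPanel-class]; a missing call has \code{NA} in both allele slots.
#'
#' @slot individuals character vector of individual ids.
#' @slot pop character vector of population tags, one per individual.
#' @slot lociIds character vector of locus ids (panel order).
#' @slot a1,a2 integer matrices (individuals x loci) of allele indices with
#'   \code{a1 <= a2}; both \code{NA} where the call is missing.
#' @seealso [GenotypeTable()], [missingFraction()], [corruptGenotypes()]
#' @export
setClass("GenotypeTable",
  representation(
    individuals = "character",
    pop = "character",
    lociIds = "character",
    a1 = "matrix",
    a2 = "matrix"
  )
)

setValidity("GenotypeTable", function(object) {
  n <- length(object@individuals)
  L <- length(object@lociIds)
  msg <- character()
  if (!all(dim(object@a1) == c(n, L)) || !all(dim(object@a2) == c(n, L)))
    msg <- c(msg, "allele matrices must be individuals x loci")
  if (!identical(is.na(object@a1), is.na(object@a2)))
    msg <- c(msg, "a1 and a2 must share the same missingness pattern")
  ok <- !is.na(object@a1)
  if (any(object@a1[ok] > object@a2[ok]))
    msg <- c(msg, "calls must be stored with a1 <= a2")
  if (any(object@a1[ok] < 1L))
    msg <- c(msg, "allele indices must be >= 1")
  if (anyDuplicated(object@individuals))
    msg <- c(msg, "individual ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele indices; pairs
#'   are reordered so \code{a1 <= a2} and \code{NA} marks missing calls.
#' @param individuals character ids (default In).
#' @param pop population tag(s), recycled.
#' @param lociIds locus ids, or a [SnpPanel-class] to take them from.
#' @return A [GenotypeTable-class].
#' @export
GenotypeTable <- function(a1, a2, individuals = NULL, pop = "pop",
                          lociIds = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  n <- nrow(a1)
  if (is.null(individuals)) individuals <- paste0("I", seq_len(n))
  if (is(lociIds, "SnpPanel")) lociIds <- lociIds@ids
  if (is.null(lociIds)) lociIds <- paste0("L", seq_len(ncol(a1)))
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- NULL
  new("GenotypeTable", individuals = as.character(individuals),
      pop = rep_len(as.character(pop), n), lociIds = as.character(lociIds),
      a1 = a1, a2 = a2)
}

#' Assignment criteria for the two-step single-parent test
#'
#' @slot m integer, maximum allowable count of Mendelian incompatibilities.
#' @slot c numeric, log-likelihood-ratio acceptance threshold (natural log).
#' @slot maxMissFrac numeric, per-sample missing-data cap (default 0.10).
#' @slot exclusionBound numeric, maximum tolerated probability of excluding a
#'   true parent-offspring pair at the MI step (default 1e-4).
#' @seealso [assignmentCriteria()], [miThreshold()], [assignSingleParents()]
#' @export
setClass("AssignmentCriteria",
  representation(m = "integer", c = "numeric", maxMissFrac = "numeric",
                 exclusionBound = "numeric")
)

setValidity("AssignmentCriteria", function(object) {
  msg <- character()
  if (object@m < 0L) msg <- c(msg, "m must be >= 0")
  if (object@maxMissFrac < 0 || object@maxMissFrac > 1)
    msg <- c(msg, "maxMissFrac must lie in [0, 1]")
  if (object@exclusionBound <= 0 || object@exclusionBound >= 1)
    msg <- c(msg, "exclusionBound must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct assignment criteria
#'
#' @param m maximum allowable MI count.
#' @param c LLR acceptance threshold (natural-log scale).
#' @param maxMissFrac per-sample missing fraction cap.
#' @param exclusionBound probability bound used when computing m.
#' @return An [AssignmentCriteria-class].
#' @export
assignmentCriteria <- function(m, c = 0, maxMissFrac = 0.10,
                               exclusionBound = 1e-4) {
  new("AssignmentCriteria", m = as.integer(m), c = as.numeric(c),
      maxMissFrac = as.numeric(maxMissFrac),
      exclusionBound = as.numeric(exclusionBound))
}

#' Stratum-size distribution over observed MI counts
#'
#' Probabilities \eqn{p_j} that a pair of a given true relationship shows
#' exactly \eqn{j} observed Mendelian incompatibilities while both individuals
#' stay within the allowed number of missing genotypes; everything else
#' (MI count above \code{m} or a missing-data cap violation) is lumped into
#' \code{excludedMass}.
#'
#' @slot p numeric vector of stratum sizes, \code{p[j+1]} for j MIs.
#' @slot excludedMass probability of the lumped excluded states.
#' @slot relationship character, the true relationship.
#' @slot m integer MI cap.
#' @slot U integer per-individual missing-count cap.
#' @slot slices list of per-locus forward-probability slices (kept when the
#'   distribution will seed backward sampling; otherwise empty).
#' @seealso [stratumSizes()], [samplePairsInStratum()]
#' @export
setClass("StratumDistribution",
  representation(p = "numeric", excludedMass = "numeric",
                 relationship = "character", m = "integer", U = "integer",
                 slices = "list")
)

setValidity("StratumDistribution", function(object) {
  tot <- sum(object@p) + object@excludedMass
  if (abs(tot - 1) > 1e-10)
    return("stratum sizes plus excluded mass must sum to 1")
  if (any(object@p < -1e-15))
    return("stratum sizes must be non-negative")
  TRUE
})
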