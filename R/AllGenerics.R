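#' @include AllClasses.R
NULL

#' Accessors for SnpPanel and GenotypeTable
#'
#' \code{nLoci} and \code{lociIds} report panel/table dimensions;
#' \code{alleleFreqs}, \code{errorRate} and \code{missingRate} expose the
#' locus-level model parameters; \code{nIndividuals}, \code{individualIds},
#' \code{populationTags} and \code{missingFraction} describe a genotype table.
#'
#' @param x a [SnpPanel-class] or [GenotypeTable-class].
#' @param value replacement value.
#' @return The requested component; setters return the modified object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))
#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))
#' @rdname accessors
#' @export
setGeneric("alleleFreqs<-", function(x, value) standardGeneric("alleleFreqs<-"))
#' @rdname accessors
#' @export
setGeneric("errorRate", function(x) standardGeneric("errorRate"))
#' @rdname accessors
#' @export
setGeneric("errorRate<-", function(x, value) standardGeneric("errorRate<-"))
#' @rdname accessors
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))
#' @rdname accessors
#' @export
setGeneric("missingRate<-", function(x, value) standardGeneric("missingRate<-"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("populationTags", function(x) standardGeneric("populationTags"))
#' @rdname accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname accessors
#' @export
setMethod("nLoci", "SnpPanel", function(x) length(x@ids))
#' @rdname accessors
#' @export
setMethod("lociIds", "SnpPanel", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("alleleFreqs", "SnpPanel", function(x) {
  stats::setNames(x@freqs, x@ids)
})
#' @rdname accessors
#' @export
setReplaceMethod("alleleFreqs", "SnpPanel", function(x, value) {
  x@freqs <- unname(value)
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("errorRate", "SnpPanel", function(x) x@epsilon)
#' @rdname accessors
#' @export
setReplaceMethod("errorRate", "SnpPanel", function(x, value) {
  x@epsilon <- rep_len(as.numeric(value), nLoci(x))
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("missingRate", "SnpPanel", function(x) x@missRate)
#' @rdname accessors
#' @export
setReplaceMethod("missingRate", "SnpPanel", function(x, value) {
  x@missRate <- rep_len(as.numeric(value), nLoci(x))
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("nLoci", "GenotypeTable", function(x) length(x@lociIds))
#' @rdname accessors
#' @export
setMethod("lociIds", "GenotypeTable", function(x) x@lociIds)
#' @rdname accessors
#' @export
setMethod("nIndividuals", "GenotypeTable", function(x) length(x@individuals))
#' @rdname accessors
#' @export
setMethod("individualIds", "GenotypeTable", function(x) x@individuals)
#' @rdname accessors
#' @export
setMethod("populationTags", "GenotypeTable", function(x) x@pop)
#' @rdname accessors
#' @export
setMethod("missingFraction", "GenotypeTable", function(x) {
  stats::setNames(rowMeans(is.na(x@a1)), x@individuals)
})

#' @describeIn accessors subset a GenotypeTable by individuals (i, ids or
#'   indices) and/or loci (j, indices).
#' @param i,j,...,drop standard subsetting arguments.
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@individuals)
  if (is.character(i)) i <- match(i, x@individuals)
  if (missing(j)) j <- seq_along(x@lociIds)
  new("GenotypeTable", individuals = x@individuals[i], pop = x@pop[i],
      lociIds = x@lociIds[j],
      a1 = x@a1[i, j, drop = FALSE], a2 = x@a2[i, j, drop = FALSE])
})

setMethod("show", "SnpPanel", function(object) {
  L <- nLoci(object)
  cat("SnpPanel with", L, "loci\n")
  k <- lengths(object@alleles)
  cat("  alleles per locus:", paste(range(k), collapse = "-"), "\n")
  cat("  per-allele error rate:",
      paste(format(range(object@epsilon), digits = 3), collapse = "-"), "\n")
  cat("  missing-call rate:",
      paste(format(range(object@missRate), digits = 3), collapse = "-"), "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nIndividuals(object), "individuals x",
      nLoci(object), "loci\n")
  cat("  populations:", paste(unique(object@pop), collapse = ", "), "\n")
  mf <- missingFraction(object)
  cat("  missing fraction: mean", format(mean(mf), digits = 3),
      "max", format(max(mf), digits = 3), "\n")
})

setMethod("show", "AssignmentCriteria", function(object) {
  cat("AssignmentCriteria: m =", object@m, ", c =", object@c,
      ", maxMissFrac =", object@maxMissFrac,
      ", exclusionBound =", object@exclusionBound, "\n")
})

setMethod("show", "StratumDistribution", function(object) {
  cat("StratumDistribution (", object@relationship, "), m = ", object@m,
      ", U = ", object@U, "\n", sep = "")
  cat("  p_j:", paste(format(object@p, digits = 4), collapse = " "), "\n")
  cat("  excluded mass:", format(object@excludedMass, digits = 4), "\n")
})

#' Stratum sizes of a StratumDistribution
#' @param x a [StratumDistribution-class].
#' @return Named numeric vector of stratum probabilities.
#' @export
strataSizes <- function(x) {
  stopifnot(is(x, "StratumDistribution"))
  stats::setNames(x@p, paste0("mi", seq_along(x@p) - 1L))
}

#' Excluded probability mass of a StratumDistribution
#' @param x a [StratumDistribution-class].
#' @return Probability that a pair falls outside all retained strata.
#' @export
excludedMass <- function(x) {
  stopifnot(is(x, "StratumDistribution"))
  x@excludedMass
}
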