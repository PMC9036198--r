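#' @include mi-engine.R
NULL

#' Extract one individual's calls as an allele-pair matrix
#'
#' @param gt a [GenotypeTable-class].
#' @param individual individual id or row index.
#' @return Integer matrix (loci x 2) of allele indices, \code{NA} = missing.
#' @export
genotypeVector <- function(gt, individual) {
  i <- if (is.character(individual)) match(individual, gt@individuals)
       else as.integer(individual)
  if (is.na(i)) stop("unknown individual: ", individual)
  cbind(a1 = gt@a1[i, ], a2 = gt@a2[i, ])
}

## genotype-index matrix (individuals x loci, NA = missing) for fast lookups
.genoIdxMatrix <- function(gt, panel) {
  n <- nIndividuals(gt); L <- nLoci(panel)
  out <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    k <- length(panel@alleles[[l]])
    ok <- !is.na(gt@a1[, l])
    out[ok, l] <- .genoIndex(gt@a1[ok, l], gt@a2[ok, l], k)
  }
  out
}

#' Count Mendelian incompatibilities between two call vectors
#'
#' A locus is an MI when both calls are observed and the two genotypes share
#' no allele (for biallelic loci, opposing homozygotes).  Loci with any
#' missing call never count.
#'
#' @param candidate,offspring loci x 2 integer matrices of allele indices
#'   (as returned by [genotypeVector()]).
#' @param panel a [SnpPanel-class] (used for length validation).
#' @return Integer MI count.
#' @export
countMIs <- function(candidate, offspring, panel) {
  L <- nLoci(panel)
  if (nrow(candidate) != L || nrow(offspring) != L)
    stop("call vectors must have one row per panel locus")
  ok <- !is.na(candidate[, 1]) & !is.na(offspring[, 1])
  share <- candidate[, 1] == offspring[, 1] | candidate[, 1] == offspring[, 2] |
           candidate[, 2] == offspring[, 1] | candidate[, 2] == offspring[, 2]
  sum(ok & !share)
}

#' Log-likelihood ratio of parent-offspring versus unrelated
#'
#' Sums, over loci where both calls are observed, the log of the probability
#' of the observed genotype pair under a parent-offspring relationship minus
#' the log probability under unrelatedness, each marginalising the unknown
#' true genotypes over the genotyping-error model.  Loci with a missing call
#' contribute zero (the missing-data likelihood is identical under both
#' hypotheses and cancels).  Natural-log scale.
#'
#' @inheritParams countMIs
#' @return Numeric LLR (may be \code{-Inf} at \code{epsilon = 0} for pairs
#'   with a Mendelian impossibility).
#' @export
pairLLR <- function(candidate, offspring, panel) {
  L <- nLoci(panel)
  if (nrow(candidate) != L || nrow(offspring) != L)
    stop("call vectors must have one row per panel locus")
  tables <- .panelTables(panel, c("PARENT_OFFSPRING", "UNRELATED"))
  r <- 0
  for (l in seq_len(L)) {
    if (is.na(candidate[l, 1]) || is.na(offspring[l, 1])) next
    k <- tables[[l]]$k
    g1 <- .genoIndex(candidate[l, 1], candidate[l, 2], k)
    g2 <- .genoIndex(offspring[l, 1], offspring[l, 2], k)
    r <- r + tables[[l]]$llr[g1, g2]
  }
  r
}

#' Two-step single-parent assignment
#'
#' Evaluates every QC-passing candidate x offspring pair.  Step one drops
#' pairs with more than \code{m} observed Mendelian incompatibilities; step
#' two computes the parent-offspring versus unrelated LLR for the survivors
#' and accepts pairs with LLR at or above the threshold \code{c}.  Samples
#' whose missing-call fraction exceeds \code{maxMissFrac} are excluded
#' before any comparison.
#'
#' @param candidates,offspring [GenotypeTable-class] objects of observed
#'   calls.
#' @param panel a [SnpPanel-class] with frequencies, error and missing rates.
#' @param criteria an [AssignmentCriteria-class].
#' @return A data.frame with one row per pair passing the MI filter:
#'   \code{offspring_id}, \code{candidate_id}, \code{mi_count}, \code{llr},
#'   \code{accepted}, and \code{multiple_flag} (set on every accepted record
#'   of an offspring with more than one accepted candidate).  The numbers of
#'   QC-passing candidates and offspring are attached as attributes
#'   \code{"nCandidates"} and \code{"nOffspring"}.
#' @export
assignSingleParents <- function(candidates, offspring, panel, criteria) {
  stopifnot(is(criteria, "AssignmentCriteria"))
  keepC <- missingFraction(candidates) <= criteria@maxMissFrac
  keepO <- missingFraction(offspring) <= criteria@maxMissFrac
  if (any(!keepC) || any(!keepO))
    message(sum(!keepC), " candidate(s) and ", sum(!keepO),
            " offspring excluded for missing data above ",
            criteria@maxMissFrac)
  empty <- data.frame(offspring_id = character(), candidate_id = character(),
                      mi_count = integer(), llr = numeric(),
                      accepted = logical(), multiple_flag = logical())
  if (!any(keepC)) {
    warning("no QC-passing candidate parents")
    return(structure(empty, nCandidates = 0L, nOffspring = sum(keepO)))
  }
  if (!any(keepO))
    return(structure(empty, nCandidates = sum(keepC), nOffspring = 0L))
  candIds <- candidates@individuals[keepC]
  offIds <- offspring@individuals[keepO]
  tables <- .panelTables(panel, c("PARENT_OFFSPRING", "UNRELATED"))
  candG <- .genoIdxMatrix(candidates, panel)[keepC, , drop = FALSE]
  offG <- .genoIdxMatrix(offspring, panel)[keepO, , drop = FALSE]
  miMasks <- lapply(tables, function(tb) {
    mm <- tb$mi; storage.mode(mm) <- "integer"; mm
  })
  llrTabs <- lapply(tables, `[[`, "llr")
  res <- cpp_pairwise_assign(candG, offG, miMasks, llrTabs,
                             as.integer(criteria@m))
  out <- data.frame(offspring_id = offIds[res$offspring],
                    candidate_id = candIds[res$candidate],
                    mi_count = res$mi, llr = res$llr,
                    accepted = res$llr >= criteria@c,
                    multiple_flag = FALSE)
  nAcc <- table(out$offspring_id[out$accepted])
  multi <- names(nAcc)[nAcc > 1L]
  out$multiple_flag <- out$accepted & out$offspring_id %in% multi
  out <- out[order(out$offspring_id, -out$llr), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, nCandidates = length(candIds), nOffspring = length(offIds))
}

## per-locus probability that a TRUE trio shows an observed trio
## incompatibility under the error model (all three genotypes observed)
.trioMIprobs <- function(panel) {
  vapply(seq_len(nLoci(panel)), function(l) {
    p <- panel@freqs[[l]]
    k <- length(p)
    g <- .genoEnum(k)
    G <- nrow(g)
    hwe <- .hweProbs(p)
    E <- .errMatrix(k, panel@epsilon[l])
    ## Mendelian transmission: P(child | dam, sire)
    M <- array(0, c(G, G, G))
    for (d in seq_len(G)) for (s in seq_len(G)) {
      for (ad in g[d, ]) for (as in g[s, ]) {
        ci <- .genoIndex(min(ad, as), max(ad, as), k)
        M[d, s, ci] <- M[d, s, ci] + 0.25
      }
    }
    tru <- array(0, c(G, G, G))
    for (d in seq_len(G)) for (s in seq_len(G))
      tru[d, s, ] <- hwe[d] * hwe[s] * M[d, s, ]
    ## apply the observation error to each member in turn
    contract <- function(A, axis) {
      A <- aperm(A, c(axis, setdiff(1:3, axis)))
      dim(A) <- c(G, G * G)
      B <- t(E) %*% A
      dim(B) <- c(G, G, G)
      aperm(B, order(c(axis, setdiff(1:3, axis))))
    }
    obs <- contract(contract(contract(tru, 1), 2), 3)
    ## incompatibility: child not obtainable from one allele of each parent
    inc <- array(FALSE, c(G, G, G))
    for (d in seq_len(G)) for (s in seq_len(G)) for (cc in seq_len(G)) {
      o1 <- g[cc, 1]; o2 <- g[cc, 2]
      comp <- (o1 %in% g[d, ] && o2 %in% g[s, ]) ||
              (o2 %in% g[d, ] && o1 %in% g[s, ])
      inc[d, s, cc] <- !comp
    }
    sum(obs[inc])
  }, numeric(1))
}

#' Maximum allowable trio incompatibilities for a true parent pair
#'
#' Analogue of [miThreshold()] for (dam, sire, offspring) trios: the smallest
#' cap such that a true trio with all genotypes observed exceeds it with
#' probability below \code{exclusionBound}, using the Poisson-binomial
#' distribution of per-locus trio incompatibilities under the error model.
#' Trio incompatibilities arise from genotyping error far more often than
#' pairwise opposing homozygotes (any of the six alleles can break
#' compatibility), so this cap is larger than the pairwise \code{m}.
#'
#' @inheritParams miThreshold
#' @return Integer cap with attribute \code{"exclusionProb"}.
#' @export
trioMIThreshold <- function(panel, exclusionBound = 1e-4) {
  stopifnot(exclusionBound > 0, exclusionBound < 1)
  P <- .poisbinDP(.trioMIprobs(panel))
  cum <- cumsum(P)
  m <- which(1 - cum < exclusionBound)[1] - 1L
  structure(as.integer(m), exclusionProb = 1 - cum[m + 1L])
}

## trio MI count: loci where the offspring genotype cannot be formed from one
## allele of each putative parent (missing calls skipped)
.trioMIcount <- function(dam, sire, off) {
  ok <- !is.na(dam[, 1]) & !is.na(sire[, 1]) & !is.na(off[, 1])
  comp <- (dam[, 1] == off[, 1] | dam[, 2] == off[, 1]) &
          (sire[, 1] == off[, 2] | sire[, 2] == off[, 2]) |
          (dam[, 1] == off[, 2] | dam[, 2] == off[, 2]) &
          (sire[, 1] == off[, 1] | sire[, 2] == off[, 1])
  sum(ok & !comp)
}

#' Paired-parent assignment helper
#'
#' Combines accepted single-parent assignments into (dam, sire) pairs for
#' offspring with accepted candidates of both sexes, requiring the trio to
#' be Mendelian-consistent (offspring genotype obtainable from one allele of
#' each parent) at all but at most \code{m} loci.  The best pair per
#' offspring by summed LLR is reported.  This is deliberately simple
#' plumbing so simulated studies can run end to end; production paired
#' analyses typically use dedicated trio software.
#'
#' @inheritParams assignSingleParents
#' @param sex named character vector ("F"/"M") giving each candidate's sex.
#' @param single optional precomputed result of [assignSingleParents()].
#' @param mTrio trio-incompatibility cap; default from [trioMIThreshold()]
#'   at the criteria's exclusion bound.
#' @return A data.frame: \code{offspring_id}, \code{dam_id}, \code{sire_id},
#'   \code{llr} (sum of the two single-parent LLRs), \code{trio_mi}.
#' @export
assignParentPairs <- function(candidates, offspring, panel, criteria, sex,
                              single = NULL, mTrio = NULL) {
  if (is.null(single))
    single <- assignSingleParents(candidates, offspring, panel, criteria)
  if (is.null(mTrio))
    mTrio <- trioMIThreshold(panel, criteria@exclusionBound)
  acc <- single[single$accepted, , drop = FALSE]
  out <- data.frame(offspring_id = character(), dam_id = character(),
                    sire_id = character(), llr = numeric(),
                    trio_mi = integer())
  if (nrow(acc) == 0L) return(out)
  acc$sex <- unname(sex[acc$candidate_id])
  for (oid in unique(acc$offspring_id)) {
    rows <- acc[acc$offspring_id == oid, , drop = FALSE]
    dams <- rows[rows$sex == "F", , drop = FALSE]
    sires <- rows[rows$sex == "M", , drop = FALSE]
    if (nrow(dams) == 0L || nrow(sires) == 0L) next
    offv <- genotypeVector(offspring, oid)
    best <- NULL
    for (di in seq_len(nrow(dams))) for (si in seq_len(nrow(sires))) {
      tm <- .trioMIcount(genotypeVector(candidates, dams$candidate_id[di]),
                         genotypeVector(candidates, sires$candidate_id[si]),
                         offv)
      if (tm > mTrio) next
      tot <- dams$llr[di] + sires$llr[si]
      if (is.null(best) || tot > best$llr)
        best <- data.frame(offspring_id = oid,
                           dam_id = dams$candidate_id[di],
                           sire_id = sires$candidate_id[si],
                           llr = tot, trio_mi = tm)
    }
    if (!is.null(best)) out <- rbind(out, best)
  }
  rownames(out) <- NULL
  out
}
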