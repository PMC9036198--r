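#' @include panel-model.R
NULL

## event order used throughout (and in the C++ backward sampler):
## 1 both observed, no MI; 2 both observed, MI; 3 candidate missing only;
## 4 offspring missing only; 5 both missing.
.EVENT_NAMES <- c("obs_noMI", "obs_MI", "cand_missing", "off_missing",
                  "both_missing")

## L x 5 matrix of per-locus event probabilities for a relationship
.eventProbMatrix <- function(panel, rel, tables) {
  pm <- panel@missRate
  pmi <- vapply(tables, function(tb) sum(tb$O[[rel]][tb$mi]), numeric(1))
  cbind((1 - pm)^2 * (1 - pmi), (1 - pm)^2 * pmi,
        pm * (1 - pm), (1 - pm) * pm, pm^2)
}

#' Per-locus probabilities of the MI/missing events
#'
#' For one locus and a true relationship, the probabilities of the five
#' per-locus outcomes of a candidate-offspring comparison: both genotypes
#' observed without a Mendelian incompatibility, both observed with an MI,
#' only the candidate's call missing, only the offspring's call missing, and
#' both missing.  An MI can only be observed when neither call is missing;
#' missingness is independent between the two individuals.
#'
#' @param panel a [SnpPanel-class].
#' @param locus locus index or id.
#' @param rel relationship name, see [relationshipNames()].
#' @return Named numeric vector of five probabilities summing to 1.
#' @export
perLocusEventProbs <- function(panel, locus, rel) {
  l <- .locusPos(panel, locus)
  O <- observedPairDistribution(panel, l, rel)
  pmi <- sum(O[.miMask(length(panel@freqs[[l]]))])
  pm <- panel@missRate[l]
  stats::setNames(
    c((1 - pm)^2 * (1 - pmi), (1 - pm)^2 * pmi,
      pm * (1 - pm), (1 - pm) * pm, pm^2),
    .EVENT_NAMES)
}

## Poisson-binomial distribution over counts by dynamic programming
.poisbinDP <- function(q) {
  P <- c(1, numeric(length(q)))
  for (qi in q) {
    shifted <- c(0, P[-length(P)]) * qi
    P <- P * (1 - qi) + shifted
  }
  P
}

#' Maximum allowable MI count for a true parent-offspring pair
#'
#' Computes the smallest threshold \code{m} such that a true parent-offspring
#' pair with all genotypes observed shows more than \code{m} Mendelian
#' incompatibilities with probability below \code{exclusionBound}.  The MI
#' count under the per-allele error model is Poisson-binomial over loci; its
#' distribution is evaluated with the forward recursion (a dynamic program
#' over the running MI count).
#'
#' @param panel a [SnpPanel-class] with frequencies and error rates set.
#' @param exclusionBound maximum tolerated probability of excluding a true
#'   pair (default 1e-4).
#' @return Integer \code{m}, with attribute \code{"exclusionProb"} giving the
#'   attained probability \code{P(MI count > m)}.
#' @examples
#' pan <- simulatePanel(50, seed = 1)
#' miThreshold(pan)
#' @export
miThreshold <- function(panel, exclusionBound = 1e-4) {
  stopifnot(exclusionBound > 0, exclusionBound < 1)
  tables <- .panelTables(panel)
  q <- vapply(tables, function(tb)
    sum(tb$O[["PARENT_OFFSPRING"]][tb$mi]), numeric(1))
  P <- .poisbinDP(q)
  tail <- rev(cumsum(rev(P)))          # tail[m+2] = P(count > m)
  m <- which(c(tail[-1], 0) < exclusionBound)[1] - 1L
  structure(as.integer(m), exclusionProb = sum(P[-seq_len(m + 1L)]))
}

#' Distribution of one individual's missing-genotype count
#'
#' Poisson-binomial distribution of the number of missing calls across loci
#' for a single individual, given the per-locus missing rates, together with
#' the probability of passing the missing-data filter (count at most
#' \code{U = floor(maxMissFrac * L)}).
#'
#' @param panel a [SnpPanel-class] with missing rates set.
#' @param maxMissFrac per-sample missing fraction cap (default 0.10).
#' @return List with \code{probs} (counts 0..L), \code{U}, and \code{pPass}.
#' @export
missingCountDistribution <- function(panel, maxMissFrac = 0.10) {
  L <- nLoci(panel)
  U <- floor(maxMissFrac * L)
  probs <- .poisbinDP(panel@missRate)
  names(probs) <- 0:L
  list(probs = probs, U = as.integer(U), pPass = sum(probs[seq_len(U + 1L)]))
}

#' Stratum sizes of the MI/missing Markov chain
#'
#' Runs the forward recursion of the Markov chain whose state after locus
#' \eqn{i} is (observed MI count, missing calls in candidate, missing calls
#' in offspring), starting from (0, 0, 0).  States exceeding the MI cap
#' \code{m} or the per-individual missing cap \code{U} are lumped immediately
#' into an absorbing excluded state.  The stratum size \eqn{p_j} is the
#' probability of ending with exactly \eqn{j} MIs while both individuals pass
#' the missing-data filter (the stratum sizes are unconditional, i.e. they
#' include the pass-filter event).
#'
#' @param panel a [SnpPanel-class].
#' @param rel relationship name.
#' @param m MI cap (from [miThreshold()] or user-chosen).
#' @param maxMissFrac per-sample missing fraction cap.
#' @param keepSlices keep the per-locus forward slices (needed to seed
#'   backward sampling; ~\code{(L+1)(m+1)(U+1)^2} doubles).
#' @param tables internal precomputed locus tables (optional).
#' @return A [StratumDistribution-class].
#' @export
stratumSizes <- function(panel, rel, m, maxMissFrac = 0.10,
                         keepSlices = FALSE, tables = NULL) {
  L <- nLoci(panel)
  m <- as.integer(m)
  if (m > L || m < 0L) stop("m must lie in 0..L")
  U <- as.integer(floor(maxMissFrac * L))
  if (is.null(tables)) tables <- .panelTables(panel)
  pa <- .eventProbMatrix(panel, rel, tables)
  P <- array(0, dim = c(m + 1L, U + 1L, U + 1L))
  P[1, 1, 1] <- 1
  excluded <- 0
  slices <- if (keepSlices) vector("list", L + 1L)
  if (keepSlices) slices[[1L]] <- P
  for (i in seq_len(L)) {
    e <- pa[i, ]
    N <- e[1] * P
    if (m >= 1L)
      N[2:(m + 1), , ] <- N[2:(m + 1), , , drop = FALSE] +
        e[2] * P[1:m, , , drop = FALSE]
    excluded <- excluded + e[2] * sum(P[m + 1, , ])
    if (U >= 1L) {
      N[, 2:(U + 1), ] <- N[, 2:(U + 1), , drop = FALSE] +
        e[3] * P[, 1:U, , drop = FALSE]
      N[, , 2:(U + 1)] <- N[, , 2:(U + 1), drop = FALSE] +
        e[4] * P[, , 1:U, drop = FALSE]
      N[, 2:(U + 1), 2:(U + 1)] <- N[, 2:(U + 1), 2:(U + 1), drop = FALSE] +
        e[5] * P[, 1:U, 1:U, drop = FALSE]
    }
    excluded <- excluded + e[3] * sum(P[, U + 1, ]) + e[4] * sum(P[, , U + 1]) +
      e[5] * (sum(P[, U + 1, ]) + sum(P[, , U + 1]) - sum(P[, U + 1, U + 1]))
    P <- N
    if (keepSlices) slices[[i + 1L]] <- P
  }
  new("StratumDistribution",
      p = as.numeric(apply(P, 1, sum)), excludedMass = excluded,
      relationship = rel, m = m, U = U,
      slices = if (keepSlices) slices else list())
}

#' Backward-sample observed genotype pairs within an MI stratum
#'
#' Draws observed (candidate, offspring) genotype pairs conditional on the
#' pair falling in stratum \code{j} (exactly \code{j} observed MIs, both
#' individuals within the missing-data cap), using the backward pass of the
#' forward-backward algorithm: the terminal chain state is drawn proportional
#' to its forward probability within the stratum, per-locus events are drawn
#' backwards proportional to event probability times the forward probability
#' of the implied predecessor state, and genotypes at observed loci are drawn
#' from the relationship-conditional pair distribution given that an MI is
#' present or not.
#'
#' @param panel a [SnpPanel-class].
#' @param rel relationship name.
#' @param j stratum index (number of observed MIs).
#' @param n number of pairs to draw.
#' @param criteria an [AssignmentCriteria-class] supplying \code{m} and
#'   \code{maxMissFrac}.
#' @param returnGenotypes also return the sampled calls as a pair of
#'   [GenotypeTable-class] objects.
#' @param strat optional precomputed [StratumDistribution-class] with slices
#'   (from \code{stratumSizes(..., keepSlices = TRUE)}).
#' @param tables internal precomputed locus tables (optional).
#' @return List with \code{llr} (numeric n; sum of per-locus log-likelihood
#'   ratios at loci where both calls are observed), \code{u1}, \code{u2}
#'   (missing counts), \code{mi} (= j), and when requested \code{candidate} /
#'   \code{offspring} genotype tables.
#' @export
samplePairsInStratum <- function(panel, rel, j, n, criteria,
                                 returnGenotypes = FALSE, strat = NULL,
                                 tables = NULL) {
  stopifnot(is(criteria, "AssignmentCriteria"))
  if (is.null(tables)) tables <- .panelTables(panel)
  if (is.null(strat))
    strat <- stratumSizes(panel, rel, criteria@m, criteria@maxMissFrac,
                          keepSlices = TRUE, tables = tables)
  if (length(strat@slices) == 0L)
    stop("stratum distribution must carry forward slices")
  if (j < 0L || j > strat@m) stop("stratum index must lie in 0..m")
  if (strat@p[j + 1L] <= 0)
    stop("empty stratum: p_", j, " is zero for ", rel)
  L <- nLoci(panel)
  pa <- .eventProbMatrix(panel, rel, tables)
  slices <- vapply(strat@slices, as.vector,
                   numeric(length(strat@slices[[1L]])))
  condNoMI <- vector("list", L); condMI <- vector("list", L)
  llrVecs <- vector("list", L); margCum <- vector("list", L)
  for (l in seq_len(L)) {
    tb <- tables[[l]]
    O <- tb$O[[rel]]
    no <- as.vector(O * !tb$mi); yes <- as.vector(O * tb$mi)
    condNoMI[[l]] <- cumsum(no / sum(no))
    condMI[[l]] <- if (sum(yes) > 0) cumsum(yes / sum(yes)) else yes
    llrVecs[[l]] <- as.vector(tb$llr)
    margCum[[l]] <- cumsum(tb$obsMarg)
  }
  res <- cpp_backward_sample(slices, pa, condNoMI, condMI, llrVecs, margCum,
                             as.integer(strat@m), as.integer(strat@U),
                             as.integer(j), as.integer(n),
                             isTRUE(returnGenotypes))
  out <- list(llr = res$llr, u1 = res$u1, u2 = res$u2,
              mi = rep.int(as.integer(j), n))
  if (returnGenotypes) {
    out$candidate <- .genoIdxToTable(res$genoCand, panel, "sim_candidate")
    out$offspring <- .genoIdxToTable(res$genoOff, panel, "sim_offspring")
  }
  out
}

## convert an n x L matrix of genotype indices (NA = missing) to a table
.genoIdxToTable <- function(gidx, panel, pop) {
  n <- nrow(gidx); L <- ncol(gidx)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    g <- .genoEnum(length(panel@alleles[[l]]))
    ok <- !is.na(gidx[, l])
    a1[ok, l] <- g[gidx[ok, l], 1]
    a2[ok, l] <- g[gidx[ok, l], 2]
  }
  GenotypeTable(a1, a2, individuals = paste0(pop, seq_len(n)), pop = pop,
                lociIds = panel)
}
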