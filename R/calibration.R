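#' @include mi-engine.R
NULL

#' Stratified Monte Carlo false-positive rate curve
#'
#' Estimates the per-comparison false-positive rate \eqn{\alpha(c)} -- the
#' probability that a candidate of the given (non-parent) relationship
#' passes both the MI filter and the LLR threshold -- by stratified
#' sampling over the observed MI count.  Strata above \code{m} contribute no
#' false positives and are never sampled.  Within stratum \eqn{j},
#' \code{nPerStratum} pairs are backward-sampled and
#' \deqn{\alpha(c) \approx \sum_{j=0}^{m} \frac{p_j}{n_j}
#'       \sum_{k=1}^{n_j} I\{r_{jk} \ge c\},}
#' where \eqn{p_j} is the stratum size and \eqn{r_{jk}} a sampled pair's LLR.
#' One simulation pass serves the whole threshold grid.  The Monte Carlo
#' standard error combines the within-stratum binomial variances,
#' \eqn{\sum_j (p_j^2 / n_j)\, \hat q_j (1 - \hat q_j)}.
#'
#' @param panel a [SnpPanel-class].
#' @param rel relationship name (see [relationshipNames()]).
#' @param m MI cap (from [miThreshold()]).
#' @param cGrid LLR thresholds to evaluate (default 0:20, natural-log scale).
#' @param nPerStratum simulated pairs per stratum (equal allocation).
#' @param maxMissFrac per-sample missing-data cap.
#' @param tables,strat optional precomputed internals.
#' @return data.frame with columns \code{c}, \code{relationship},
#'   \code{alpha}, \code{alpha_se}.
#' @export
falsePositiveCurve <- function(panel, rel, m, cGrid = 0:20,
                               nPerStratum = 10000, maxMissFrac = 0.10,
                               tables = NULL, strat = NULL) {
  if (nPerStratum < 100) stop("nPerStratum must be at least 100")
  if (is.null(tables)) tables <- .panelTables(panel)
  if (is.null(strat))
    strat <- stratumSizes(panel, rel, m, maxMissFrac, keepSlices = TRUE,
                          tables = tables)
  if (all(strat@p <= 0)) stop("degenerate panel: all stratum sizes are zero")
  crit <- assignmentCriteria(m, c = min(cGrid), maxMissFrac = maxMissFrac)
  alpha <- numeric(length(cGrid))
  vsum <- numeric(length(cGrid))
  for (j in 0:m) {
    pj <- strat@p[j + 1L]
    if (pj <= 0) next
    draws <- samplePairsInStratum(panel, rel, j, nPerStratum, crit,
                                  strat = strat, tables = tables)
    qhat <- vapply(cGrid, function(cc) mean(draws$llr >= cc), numeric(1))
    alpha <- alpha + pj * qhat
    vsum <- vsum + pj^2 * qhat * (1 - qhat) / nPerStratum
  }
  data.frame(c = cGrid, relationship = rel, alpha = alpha,
             alpha_se = sqrt(vsum))
}

#' Monte Carlo false-negative rate curve
#'
#' Simulates observed genotypes of true parent-offspring pairs (genotype
#' pairs drawn per locus from the relationship-conditional observed-pair
#' distribution; per-individual missing calls drawn from the one-individual
#' missing-count chain conditional on passing the missing-data cap, placed
#' across loci by its backward recursion) and records the fraction not
#' assigned at each threshold: MI count above \code{m} or LLR below \code{c}.
#'
#' @param panel a [SnpPanel-class].
#' @param m MI cap.
#' @param cGrid LLR thresholds (default 0:20).
#' @param nSim number of simulated true pairs (>= 1000).
#' @param maxMissFrac per-sample missing-data cap.
#' @param tables optional precomputed internals.
#' @return data.frame with columns \code{c}, \code{fnr}, \code{fnr_se}.
#' @export
falseNegativeCurve <- function(panel, m, cGrid = 0:20, nSim = 10000,
                               maxMissFrac = 0.10, tables = NULL) {
  if (nSim < 1000) stop("nSim must be at least 1000")
  if (is.null(tables)) tables <- .panelTables(panel)
  L <- nLoci(panel)
  U <- floor(maxMissFrac * L)
  obs1 <- .sampleMissingPatterns(panel, nSim, U)
  obs2 <- .sampleMissingPatterns(panel, nSim, U)
  both <- !(obs1 | obs2)
  mi <- integer(nSim)
  llr <- numeric(nSim)
  for (l in seq_len(L)) {
    tb <- tables[[l]]
    cum <- cumsum(as.vector(tb$O[["PARENT_OFFSPRING"]]))
    idx <- findInterval(stats::runif(nSim), cum) + 1L
    idx[idx > length(cum)] <- length(cum)
    use <- both[, l]
    mi <- mi + (use & as.vector(tb$mi)[idx])
    contrib <- as.vector(tb$llr)[idx]
    llr <- llr + ifelse(use, contrib, 0)
  }
  fnr <- vapply(cGrid, function(cc) mean(mi > m | llr < cc), numeric(1))
  data.frame(c = cGrid, fnr = fnr,
             fnr_se = sqrt(fnr * (1 - fnr) / nSim))
}

## Sample n per-individual missing patterns (n x L logical) from the
## one-individual missing-count chain conditional on total count <= U:
## forward DP on the count, then exact backward placement across loci.
.sampleMissingPatterns <- function(panel, n, U) {
  q <- panel@missRate
  L <- length(q)
  Tf <- matrix(0, L + 1L, U + 1L)   # Tf[i+1, r+1] = P(r missing in loci 1..i)
  Tf[1, 1] <- 1
  for (i in seq_len(L)) {
    Tf[i + 1, ] <- Tf[i, ] * (1 - q[i])
    if (U >= 1)
      Tf[i + 1, 2:(U + 1)] <- Tf[i + 1, 2:(U + 1)] + q[i] * Tf[i, 1:U]
  }
  fin <- Tf[L + 1, ] / sum(Tf[L + 1, ])
  r <- sample.int(U + 1L, n, replace = TRUE, prob = fin) - 1L
  out <- matrix(FALSE, n, L)
  for (i in L:1) {
    pm <- numeric(n)
    pos <- r >= 1L
    if (any(pos)) {
      denom <- Tf[i + 1, r[pos] + 1L]
      pm[pos] <- q[i] * Tf[i, r[pos]] / denom
    }
    hit <- stats::runif(n) < pm
    out[hit, i] <- TRUE
    r[hit] <- r[hit] - 1L
  }
  out
}

#' Probability a comparison involves the full sibling of the true parent
#'
#' \code{Pfs = 2 (mean full-sib family size - 1) / Np}: the expected number
#' of aunts/uncles of a random offspring among the candidate parents,
#' divided by the number of candidates, assuming all evaluated offspring are
#' offspring of the candidates and matings were between unrelated
#' individuals.  Clipped to [0, 1].
#'
#' @param familySizes integer vector of full-sib family sizes in the
#'   candidate parent dataset (singletons count as size 1).
#' @param Np number of sampled candidate parents.
#' @return Numeric Pfs.
#' @examples
#' pfsEstimate(rep(2, 50), 100)   # 0.02
#' @export
pfsEstimate <- function(familySizes, Np) {
  if (length(familySizes) == 0L) stop("empty family-size list")
  stopifnot(Np > 0, all(familySizes >= 1))
  min(max(2 * (mean(familySizes) - 1) / Np, 0), 1)
}

#' Experiment-wide expected false positives
#'
#' \code{Fp = Np * No * alpha * Pfs}: expected number of erroneous
#' single-parent assignments when the dominant error source is the full
#' sibling of the true parent.
#'
#' @param Np number of sampled candidate parents.
#' @param No number of offspring evaluated.
#' @param alpha per-comparison false-positive rate at the chosen threshold.
#' @param Pfs probability a comparison involves a full sibling of the true
#'   parent (see [pfsEstimate()]).
#' @return Expected count of false-positive assignments.
#' @examples
#' experimentWideFP(346, 1852, 0.00087, 0.0095)  # ~5.3
#' @export
experimentWideFP <- function(Np, No, alpha, Pfs) {
  stopifnot(Np >= 0, No >= 0, alpha >= 0, Pfs >= 0)
  Np * No * alpha * Pfs
}

#' Comprehensive experiment-wide false-positive estimate
#'
#' \code{N * (Pu Eu + Pa Ea + Pha Eha + Pc Epc)} over the four non-parent
#' relationship categories (unrelated, aunt/uncle, half-aunt/uncle, cousin
#' of the true parent).
#'
#' @param N total number of comparisons.
#' @param pUnrelated,pAunt,pHalfAunt,pCousin probabilities that a comparison
#'   involves each category.
#' @param eUnrelated,eAunt,eHalfAunt,eCousin per-comparison false-positive
#'   rates for each category.
#' @return Expected count of false-positive assignments.
#' @export
comprehensiveFP <- function(N, pUnrelated, pAunt, pHalfAunt, pCousin,
                            eUnrelated, eAunt, eHalfAunt, eCousin) {
  p <- c(pUnrelated, pAunt, pHalfAunt, pCousin)
  e <- c(eUnrelated, eAunt, eHalfAunt, eCousin)
  stopifnot(all(p >= 0), all(p <= 1), all(e >= 0))
  if (sum(p) > 1 + 1e-12)
    warning("relationship probabilities sum to more than 1")
  N * sum(p * e)
}

#' Select the LLR threshold meeting an experiment-wide budget
#'
#' Returns the smallest grid threshold whose implied experiment-wide
#' false-positive count \code{Np * No * alpha(c) * Pfs} is at or below the
#' budget, and reports the false-negative rate paid at that threshold.
#'
#' @param alphaCurve data.frame from [falsePositiveCurve()] (the relevant
#'   relationship, typically aunt/uncle).
#' @param Np,No,Pfs experiment-wide factors, see [experimentWideFP()].
#' @param fpBudget maximum tolerated expected false positives.
#' @param fnrCurve optional data.frame from [falseNegativeCurve()].
#' @return List with \code{c}, \code{alpha}, \code{Fp} and (when a curve is
#'   supplied) \code{fnr}.
#' @export
selectThreshold <- function(alphaCurve, Np, No, Pfs, fpBudget,
                            fnrCurve = NULL) {
  ord <- order(alphaCurve$c)
  cc <- alphaCurve$c[ord]
  fp <- Np * No * alphaCurve$alpha[ord] * Pfs
  ok <- which(fp <= fpBudget)
  if (length(ok) == 0L)
    stop("no threshold on the grid meets the false-positive budget")
  i <- ok[1]
  out <- list(c = cc[i], alpha = alphaCurve$alpha[ord][i], Fp = fp[i])
  if (!is.null(fnrCurve)) {
    j <- match(cc[i], fnrCurve$c)
    out$fnr <- if (is.na(j)) NA_real_ else fnrCurve$fnr[j]
  }
  out
}
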