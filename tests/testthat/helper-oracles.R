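# Independent oracles used across the suite: brute-force enumerations that
# never touch the package's own distribution machinery beyond elementary
# helpers.

# unordered genotypes of a k-allele locus in package enumeration order
oracleGenotypes <- function(k) {
  out <- NULL
  for (i in seq_len(k)) for (j in i:k) out <- rbind(out, c(i, j))
  out
}

oracleGenoIndex <- function(a, b, k) {
  g <- oracleGenotypes(k)
  which(g[, 1] == min(a, b) & g[, 2] == max(a, b))
}

# allele-level error kernel applied to an unordered genotype: distribution
# over observed genotype indices
oracleErrGeno <- function(a, b, eps, k) {
  A <- matrix(eps / (k - 1), k, k); diag(A) <- 1 - eps
  G <- nrow(oracleGenotypes(k))
  out <- numeric(G)
  for (x in seq_len(k)) for (y in seq_len(k))
    out[oracleGenoIndex(x, y, k)] <- out[oracleGenoIndex(x, y, k)] +
      A[a, x] * A[b, y]
  out
}

# Exhaustive pedigree enumeration of the observed (candidate, offspring)
# pair distribution for an aunt/uncle pair at one biallelic locus:
# grandparents -> two full siblings -> child of sibling 1; candidate is
# sibling 2.  Returns a G x G matrix over observed genotypes.
oracleAuntPairDist <- function(p, eps) {
  k <- length(p)
  G <- nrow(oracleGenotypes(k))
  out <- matrix(0, G, G)
  for (g1a in 1:k) for (g1b in 1:k) for (g2a in 1:k) for (g2b in 1:k) {
    pGP <- p[g1a] * p[g1b] * p[g2a] * p[g2b]
    for (s1pick in 1:2) for (s1pick2 in 1:2) {       # sibling 1 alleles
      s1a <- c(g1a, g1b)[s1pick]; s1b <- c(g2a, g2b)[s1pick2]
      for (s2pick in 1:2) for (s2pick2 in 1:2) {     # sibling 2 (candidate)
        c1 <- c(g1a, g1b)[s2pick]; c2 <- c(g2a, g2b)[s2pick2]
        for (tpick in 1:2) for (oth in 1:k) {        # child of sibling 1
          o1 <- c(s1a, s1b)[tpick]; o2 <- oth
          pr <- pGP * (1 / 2)^5 * p[oth]
          dc <- oracleErrGeno(c1, c2, eps, k)
          do <- oracleErrGeno(o1, o2, eps, k)
          out <- out + pr * outer(dc, do)
        }
      }
    }
  }
  out
}

# Brute-force single-locus LLR: double sum over all true genotype pairs
# under PO and unrelated, HWE and Mendelian transmission, error applied.
oracleLocusLLR <- function(p, eps, gObs1, gObs2) {
  k <- length(p)
  g <- oracleGenotypes(k)
  G <- nrow(g)
  hwe <- apply(g, 1, function(r)
    if (r[1] == r[2]) p[r[1]]^2 else 2 * p[r[1]] * p[r[2]])
  # P(offspring true genotype | parent true genotype)
  trans <- matrix(0, G, G)
  for (t1 in seq_len(G)) for (shared in g[t1, ]) for (oth in 1:k)
    trans[t1, oracleGenoIndex(shared, oth, k)] <-
      trans[t1, oracleGenoIndex(shared, oth, k)] + 0.5 * p[oth]
  po <- 0; un <- 0
  for (t1 in seq_len(G)) for (t2 in seq_len(G)) {
    e1 <- oracleErrGeno(g[t1, 1], g[t1, 2], eps, k)[gObs1]
    e2 <- oracleErrGeno(g[t2, 1], g[t2, 2], eps, k)[gObs2]
    po <- po + hwe[t1] * trans[t1, t2] * e1 * e2
    un <- un + hwe[t1] * hwe[t2] * e1 * e2
  }
  log(po) - log(un)
}

# Exact per-locus outcome distribution for a relationship: a list with the
# observed-pair matrix O (both observed), and missing-event probabilities.
# Built on observedPairDistribution, which the panel-level enumerations
# below treat as a locus-level primitive (itself oracle-tested elsewhere).
oracleLocusOutcomes <- function(panel, l, rel) {
  O <- observedPairDistribution(panel, l, rel)
  pm <- missingRate(panel)[l]
  list(O = O * (1 - pm)^2, candMiss = pm * (1 - pm),
       offMiss = (1 - pm) * pm, bothMiss = pm^2)
}

# Exhaustive enumeration of stratum sizes for a small panel (<= 3 loci):
# joint over per-locus outcomes (ordered observed pairs, or missing events),
# accumulating P(j MIs, u1, u2) subject to caps m and U.
oracleStratumSizes <- function(panel, rel, m, maxMissFrac) {
  L <- nLoci(panel)
  U <- floor(maxMissFrac * L)
  share <- function(g, i, j, k) {
    ge <- oracleGenotypes(k)
    length(intersect(ge[i, ], ge[j, ])) > 0
  }
  states <- list(list(d = 0, u1 = 0, u2 = 0, pr = 1))
  for (l in seq_len(L)) {
    k <- length(alleleFreqs(panel)[[l]])
    out <- oracleLocusOutcomes(panel, l, rel)
    G <- nrow(out$O)
    newStates <- list()
    add <- function(d, u1, u2, pr) {
      key <- paste(d, u1, u2)
      cur <- newStates[[key]]
      newStates[[key]] <<- if (is.null(cur)) pr else cur + pr
    }
    for (st in states) {
      for (i in seq_len(G)) for (j in seq_len(G)) {
        dd <- st$d + as.integer(!share(NULL, i, j, k))
        add(dd, st$u1, st$u2, st$pr * out$O[i, j])
      }
      add(st$d, st$u1 + 1, st$u2, st$pr * out$candMiss)
      add(st$d, st$u1, st$u2 + 1, st$pr * out$offMiss)
      add(st$d, st$u1 + 1, st$u2 + 1, st$pr * out$bothMiss)
    }
    states <- lapply(names(newStates), function(key) {
      v <- as.integer(strsplit(key, " ")[[1]])
      list(d = v[1], u1 = v[2], u2 = v[3], pr = newStates[[key]])
    })
  }
  p <- numeric(m + 1)
  for (st in states)
    if (st$d <= m && st$u1 <= U && st$u2 <= U)
      p[st$d + 1] <- p[st$d + 1] + st$pr
  list(p = p, excluded = 1 - sum(p))
}

# Exact conditional distribution of observed genotype-pair vectors given a
# stratum, for a small no-missing panel: joint over per-locus ordered pairs.
oraclePairVectorDist <- function(panel, rel, j) {
  L <- nLoci(panel)
  Os <- lapply(seq_len(L), function(l)
    observedPairDistribution(panel, l, rel))
  G <- nrow(Os[[1]])
  mi <- sapply(seq_len(G), function(i) sapply(seq_len(G), function(jj) {
    ge <- oracleGenotypes(length(alleleFreqs(panel)[[1]]))
    length(intersect(ge[i, ], ge[jj, ])) == 0
  }))
  combos <- expand.grid(rep(list(seq_len(G * G)), L))
  pr <- apply(combos, 1, function(row) {
    prod(vapply(seq_len(L), function(l) {
      i <- (row[l] - 1) %% G + 1; jj <- (row[l] - 1) %/% G + 1
      Os[[l]][i, jj]
    }, numeric(1)))
  })
  nmi <- apply(combos, 1, function(row) {
    sum(vapply(seq_len(L), function(l) {
      i <- (row[l] - 1) %% G + 1; jj <- (row[l] - 1) %/% G + 1
      mi[jj, i]  # mi is symmetric for biallelic loci
    }, logical(1)))
  })
  keep <- nmi == j
  list(combos = combos[keep, , drop = FALSE], pr = pr[keep] / sum(pr[keep]))
}

# small fixed test panels
tinyPanel <- function(L = 3, p = c(0.3, 0.5, 0.2)[seq_len(L)],
                      eps = 0.01, miss = 0.05) {
  SnpPanel(paste0("t", seq_len(L)),
           freqs = lapply(p, function(q) c(q, 1 - q)),
           epsilon = eps, missRate = miss)
}
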