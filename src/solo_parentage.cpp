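#include <Rcpp.h>
using namespace Rcpp;

// All randomness uses R's RNG stream so results are reproducible with
// set.seed() from R.

static inline int sampleCum(const NumericVector &cum) {
  // cum: cumulative probabilities, last entry ~ 1
  double u = unif_rand() * cum[cum.size() - 1];
  int n = cum.size();
  for (int i = 0; i < n; ++i)
    if (u <= cum[i]) return i;
  return n - 1;
}

static inline int sampleAllele(const NumericVector &cumFreq) {
  return sampleCum(cumFreq);
}

// genotype index (0-based) of unordered allele pair, alleles 0-based
static inline int genoIdx(int a, int b, int k) {
  if (a > b) { int t = a; a = b; b = t; }
  // genotypes enumerated (0,0),(0,1),..,(0,k-1),(1,1),..
  return a * k - a * (a - 1) / 2 + (b - a);
}

static inline int misread(int a, int k) {
  // substitute an allele drawn uniformly from the other k-1 alleles
  int r = (int)(unif_rand() * (k - 1));
  if (r >= k - 1) r = k - 2;
  return r >= a ? r + 1 : r;
}

// Simulate n candidate/offspring pairs of a given true relationship through
// explicit mini-pedigrees at the allele level, apply the per-allele error
// model and (optionally) missingness, and return per-pair summaries:
// observed MI count, summed LLR over loci with both calls observed, and the
// per-individual missing-call counts.
// relCode: 0 unrelated, 1 parent-offspring, 2 aunt/uncle, 3 half-aunt/uncle,
// 4 cousin-of-parent.
// [[Rcpp::export]]
DataFrame cpp_pair_stats(List cumFreqs, NumericVector eps, NumericVector miss,
                         int relCode, List llrTabs, int n, bool applyMissing) {
  int L = cumFreqs.size();
  std::vector<NumericVector> cf(L);
  std::vector<NumericMatrix> llr(L);
  for (int l = 0; l < L; ++l) {
    cf[l] = as<NumericVector>(cumFreqs[l]);
    llr[l] = as<NumericMatrix>(llrTabs[l]);
  }
  IntegerVector mi(n), nm1(n), nm2(n);
  NumericVector rsum(n);
  RNGScope scope;
  for (int s = 0; s < n; ++s) {
    int miCount = 0, m1 = 0, m2 = 0;
    double r = 0.0;
    for (int l = 0; l < L; ++l) {
      const NumericVector &f = cf[l];
      int k = f.size();
      int c1, c2, o1, o2;  // candidate and offspring alleles (true)
      switch (relCode) {
      case 0: {  // unrelated: two independent HWE genotypes
        c1 = sampleAllele(f); c2 = sampleAllele(f);
        o1 = sampleAllele(f); o2 = sampleAllele(f);
        break; }
      case 1: {  // parent-offspring
        c1 = sampleAllele(f); c2 = sampleAllele(f);
        o1 = (unif_rand() < 0.5) ? c1 : c2;
        o2 = sampleAllele(f);
        break; }
      case 2: {  // aunt/uncle: grandparents -> two full sibs -> child of one
        int g1a = sampleAllele(f), g1b = sampleAllele(f);
        int g2a = sampleAllele(f), g2b = sampleAllele(f);
        int s1a = (unif_rand() < 0.5) ? g1a : g1b;
        int s1b = (unif_rand() < 0.5) ? g2a : g2b;
        c1 = (unif_rand() < 0.5) ? g1a : g1b;          // sib 2
        c2 = (unif_rand() < 0.5) ? g2a : g2b;
        o1 = (unif_rand() < 0.5) ? s1a : s1b;          // child of sib 1
        o2 = sampleAllele(f);
        break; }
      case 3: {  // half-aunt/uncle: half sibs share one parent
        int sa = sampleAllele(f), sb = sampleAllele(f);  // shared parent
        int p1a = sampleAllele(f), p1b = sampleAllele(f);
        int p2a = sampleAllele(f), p2b = sampleAllele(f);
        int h1a = (unif_rand() < 0.5) ? sa : sb;
        int h1b = (unif_rand() < 0.5) ? p1a : p1b;
        c1 = (unif_rand() < 0.5) ? sa : sb;            // half sib 2
        c2 = (unif_rand() < 0.5) ? p2a : p2b;
        o1 = (unif_rand() < 0.5) ? h1a : h1b;          // child of half sib 1
        o2 = sampleAllele(f);
        break; }
      default: { // cousin of parent
        int g1a = sampleAllele(f), g1b = sampleAllele(f);
        int g2a = sampleAllele(f), g2b = sampleAllele(f);
        int sAa = (unif_rand() < 0.5) ? g1a : g1b;     // sib A
        int sAb = (unif_rand() < 0.5) ? g2a : g2b;
        int sBa = (unif_rand() < 0.5) ? g1a : g1b;     // sib B
        int sBb = (unif_rand() < 0.5) ? g2a : g2b;
        int pa = (unif_rand() < 0.5) ? sAa : sAb;      // parent (child of A)
        int pb = sampleAllele(f);
        c1 = (unif_rand() < 0.5) ? sBa : sBb;          // cousin (child of B)
        c2 = sampleAllele(f);
        o1 = (unif_rand() < 0.5) ? pa : pb;            // offspring of parent
        o2 = sampleAllele(f);
        break; }
      }
      double e = eps[l];
      if (e > 0) {
        if (unif_rand() < e) c1 = misread(c1, k);
        if (unif_rand() < e) c2 = misread(c2, k);
        if (unif_rand() < e) o1 = misread(o1, k);
        if (unif_rand() < e) o2 = misread(o2, k);
      }
      bool miss1 = false, miss2 = false;
      if (applyMissing && miss[l] > 0) {
        miss1 = unif_rand() < miss[l];
        miss2 = unif_rand() < miss[l];
      }
      if (miss1) ++m1;
      if (miss2) ++m2;
      if (miss1 || miss2) continue;
      bool share = (c1 == o1 || c1 == o2 || c2 == o1 || c2 == o2);
      if (!share) ++miCount;
      r += llr[l](genoIdx(c1, c2, k), genoIdx(o1, o2, k));
    }
    mi[s] = miCount; nm1[s] = m1; nm2[s] = m2; rsum[s] = r;
  }
  return DataFrame::create(_["mi"] = mi, _["llr"] = rsum,
                           _["nmiss1"] = nm1, _["nmiss2"] = nm2);
}

// Backward sampling of observed genotype pairs within MI stratum j.
// slices: ((m+1)(U+1)^2) x (L+1) forward probabilities (column i = state
// distribution after locus i, lumped states dropped); pa: L x 5 per-locus
// event probabilities in the order (no-MI, MI, cand-missing, off-missing,
// both-missing); condNoMI/condMI: per-locus cumulative distributions over
// ordered observed genotype-pair indices (column-major: idx = (g2)*G + g1);
// llrVecs: per-locus LLR per pair index; margCum: per-locus cumulative
// marginal observed-genotype distribution (used at one-missing loci).
// [[Rcpp::export]]
List cpp_backward_sample(NumericMatrix slices, NumericMatrix pa,
                         List condNoMI, List condMI, List llrVecs,
                         List margCum, int m, int U, int j, int n,
                         bool returnGenos) {
  int L = pa.nrow();
  int M = m + 1, UU = U + 1;
  std::vector<NumericVector> cNo(L), cMi(L), lv(L), mg(L);
  for (int l = 0; l < L; ++l) {
    cNo[l] = as<NumericVector>(condNoMI[l]);
    cMi[l] = as<NumericVector>(condMI[l]);
    lv[l] = as<NumericVector>(llrVecs[l]);
    mg[l] = as<NumericVector>(margCum[l]);
  }
  NumericVector llrOut(n);
  IntegerVector u1Out(n), u2Out(n);
  IntegerMatrix genoCand, genoOff;
  if (returnGenos) {
    genoCand = IntegerMatrix(n, L);
    genoOff = IntegerMatrix(n, L);
    std::fill(genoCand.begin(), genoCand.end(), NA_INTEGER);
    std::fill(genoOff.begin(), genoOff.end(), NA_INTEGER);
  }
  // terminal-state distribution within the stratum (over u1, u2 at d = j)
  NumericVector termCum(UU * UU);
  double acc = 0;
  for (int u2 = 0; u2 < UU; ++u2)
    for (int u1 = 0; u1 < UU; ++u1) {
      acc += slices(j + M * (u1 + UU * u2), L);
      termCum[u1 + UU * u2] = acc;
    }
  if (acc <= 0) stop("empty stratum");
  RNGScope scope;
  for (int s = 0; s < n; ++s) {
    int t = sampleCum(termCum);
    int u1 = t % UU, u2 = t / UU, d = j;
    u1Out[s] = u1; u2Out[s] = u2;
    double r = 0.0;
    for (int i = L; i >= 1; --i) {
      double w[5];
      // predecessor states for the five events
      w[0] = pa(i - 1, 0) * slices(d + M * (u1 + UU * u2), i - 1);
      w[1] = (d >= 1) ? pa(i - 1, 1) * slices(d - 1 + M * (u1 + UU * u2), i - 1) : 0.0;
      w[2] = (u1 >= 1) ? pa(i - 1, 2) * slices(d + M * (u1 - 1 + UU * u2), i - 1) : 0.0;
      w[3] = (u2 >= 1) ? pa(i - 1, 3) * slices(d + M * (u1 + UU * (u2 - 1)), i - 1) : 0.0;
      w[4] = (u1 >= 1 && u2 >= 1)
        ? pa(i - 1, 4) * slices(d + M * (u1 - 1 + UU * (u2 - 1)), i - 1) : 0.0;
      double tot = w[0] + w[1] + w[2] + w[3] + w[4];
      double u = unif_rand() * tot;
      int a = 0;
      double cumw = w[0];
      while (a < 4 && u > cumw) { ++a; cumw += w[a]; }
      int G = 0;
      switch (a) {
      case 0: {
        int p = sampleCum(cNo[i - 1]);
        r += lv[i - 1][p];
        if (returnGenos) {
          G = mg[i - 1].size();
          genoCand(s, i - 1) = p % G + 1;
          genoOff(s, i - 1) = p / G + 1;
        }
        break; }
      case 1: {
        int p = sampleCum(cMi[i - 1]);
        r += lv[i - 1][p];
        --d;
        if (returnGenos) {
          G = mg[i - 1].size();
          genoCand(s, i - 1) = p % G + 1;
          genoOff(s, i - 1) = p / G + 1;
        }
        break; }
      case 2:
        --u1;
        if (returnGenos) genoOff(s, i - 1) = sampleCum(mg[i - 1]) + 1;
        break;
      case 3:
        --u2;
        if (returnGenos) genoCand(s, i - 1) = sampleCum(mg[i - 1]) + 1;
        break;
      default:
        --u1; --u2;
        break;
      }
    }
    llrOut[s] = r;
  }
  List out = List::create(_["llr"] = llrOut, _["u1"] = u1Out,
                          _["u2"] = u2Out);
  if (returnGenos) {
    out["genoCand"] = genoCand;
    out["genoOff"] = genoOff;
  }
  return out;
}

// All-pairs MI count and LLR between candidate and offspring genotype-index
// matrices (1-based genotype indices, NA = missing).  Pairs whose MI count
// exceeds m are dropped (the MI filter); retained pairs report the full MI
// count and the summed LLR over loci with both calls observed.
// [[Rcpp::export]]
List cpp_pairwise_assign(IntegerMatrix candG, IntegerMatrix offG,
                         List miMasks, List llrTabs, int m) {
  int nc = candG.nrow(), no = offG.nrow(), L = candG.ncol();
  std::vector<IntegerMatrix> mim(L);
  std::vector<NumericMatrix> llr(L);
  for (int l = 0; l < L; ++l) {
    mim[l] = as<IntegerMatrix>(miMasks[l]);
    llr[l] = as<NumericMatrix>(llrTabs[l]);
  }
  std::vector<int> ci, oi, mis;
  std::vector<double> rs;
  for (int i = 0; i < nc; ++i) {
    for (int j2 = 0; j2 < no; ++j2) {
      int mi = 0;
      double r = 0.0;
      bool drop = false;
      for (int l = 0; l < L; ++l) {
        int g1 = candG(i, l), g2 = offG(j2, l);
        if (g1 == NA_INTEGER || g2 == NA_INTEGER) continue;
        if (mim[l](g1 - 1, g2 - 1)) {
          if (++mi > m) { drop = true; break; }
        }
        r += llr[l](g1 - 1, g2 - 1);
      }
      if (!drop) {
        ci.push_back(i + 1); oi.push_back(j2 + 1);
        mis.push_back(mi); rs.push_back(r);
      }
    }
  }
  return List::create(_["candidate"] = wrap(ci), _["offspring"] = wrap(oi),
                      _["mi"] = wrap(mis), _["llr"] = wrap(rs));
}
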