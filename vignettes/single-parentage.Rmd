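---
title: "Single-parent parentage assignment with calibrated error rates"
author: "soloParentage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-parent parentage assignment with calibrated error rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soloParentage)
```

# Scope and model

`soloParentage` assigns offspring to a single sampled candidate parent when
the other parent may belong to an unsampled population, and quantifies the
error rates of those assignments. The setting it is built for is a
parentage-based-tagging programme in a salmonid nursery lake: adults
released for volitional spawning are all genotyped, an unsampled resident
population spawns alongside them, and emigrating juveniles are genotyped at
a panel of a few hundred biallelic amplicon SNPs. An offspring assigned to
a pair of released adults reveals an assortative (released x released)
mating; an offspring assigned to exactly one released adult reveals a
disassortative mating with a resident.

All computations condition on a locus-level model that is estimated once
and then treated as known:

* **Allele frequencies** per locus, estimated from the candidate parents as
  posterior means under a Dirichlet(0.5, ..., 0.5) prior (Beta(0.5, 0.5)
  for biallelic loci): each allele count is incremented by 0.5. Loci are
  assumed to be in Hardy-Weinberg equilibrium and unlinked, and pedigrees
  inbreeding-free; relative pairs are parameterised by IBD-sharing
  coefficients (k0, k1, k2).
* **Genotyping error**, a per-allele rate `epsilon` (default 0.005, i.e.
  0.5% per allele): each allele of a true genotype is misread
  independently, the misread substituting an allele drawn uniformly from
  the locus's other alleles. For a biallelic SNP this is the unique flip
  model; the "uniform over other alleles" choice generalises it to
  microhaplotype-style loci without extra parameters. Errors never produce
  alleles absent from the panel.
* **Missing calls**, a per-locus rate estimated with the same Beta(0.5, 0.5)
  posterior mean from parents and offspring pooled, independent across
  individuals and loci.

## The two-step test

A candidate/offspring pair is evaluated in two steps.

**Step 1 (MI filter).** A locus is a Mendelian incompatibility (MI) when
both calls are observed and share no allele. The cap `m` is the smallest
integer such that a true parent-offspring pair with *no missing data*
exceeds it with probability below `exclusionBound` (default `1e-4`); since
missing data only hides MIs, pairs with missing calls are excluded even
more rarely. The MI count of a true pair is Poisson-binomial across loci,
and `miThreshold()` evaluates it by the forward recursion (a dynamic
program over the running count).

**Step 2 (LLR).** Surviving pairs are scored by the log-likelihood ratio of
parent-offspring versus unrelated, summing per-locus terms that marginalise
the true genotypes over the error model. Loci with a missing call
contribute zero: the missing-data likelihood is identical under both
hypotheses and cancels. The ratio is on the **natural-log scale** — the
threshold grid 0..20 is interpreted in those units; if another
implementation defines its ratio in a different base, thresholds rescale by
a constant. Pairs with LLR at or above `c` are accepted. All acceptances
are reported, and offspring with several accepted candidates are flagged
rather than auto-resolved, leaving the resolution to the analyst.

# Calibrating the threshold

## Stratified false-positive estimation

The per-comparison false-positive rate alpha(c) — the probability that a
candidate of a given non-parent relationship passes both steps — is
typically far too small for naive simulation. The estimator stratifies by
the observed MI count: strata above `m` contribute nothing and are never
sampled, so all simulation effort lands on the rare pairs that could
actually be accepted.

The machinery is a Markov chain whose state after each locus is (MI count,
missing calls in candidate, missing calls in offspring), starting at
(0, 0, 0), with five per-locus events: both observed without MI, both
observed with MI, only the candidate missing, only the offspring missing,
both missing. `stratumSizes()` runs the forward recursion; states breaching
the MI cap `m` or the per-individual missing cap `U = floor(maxMissFrac *
L)` are lumped immediately into an absorbing excluded state, so memory is
`O(m U^2)` per slice rather than `O(L^3)`. The stratum sizes `p_j` are
*unconditional*: they include the probability that both individuals pass
the missing-data filter, matching the estimator's definition (the
`StratumDistribution` carries the excluded mass, so a user wanting rates
conditional on passing QC can renormalise). At the package's working scale
(L around 350, m around 5, U around 35) all L+1 forward slices occupy only
a few tens of megabytes, so they are stored outright and reused by the
backward pass rather than checkpointed and recomputed.

`samplePairsInStratum()` implements the backward pass: draw the terminal
state within the stratum proportional to its forward probability, then per
locus (in reverse) draw the event proportional to event probability times
the forward probability of the implied predecessor, and finally draw
genotypes from the relationship-conditional observed-pair distribution
given MI-present or MI-absent. One simulation pass serves the entire
threshold grid: each pair's LLR is stored and thresholded afterwards, which
both saves draws and makes alpha(c) exactly non-increasing in c on shared
draws. The Monte Carlo standard error combines within-stratum binomial
variances, `sum_j (p_j^2 / n_j) q_j (1 - q_j)`. Draws are allocated equally
across strata (`nPerStratum` each); the estimator is unbiased under any
allocation, and equal allocation keeps the interface simple.

Error rates are computed separately for four relationships between the
candidate and the offspring's true parent: unrelated, aunt/uncle (full
sibling of the parent), half-aunt/uncle, and cousin of the parent, with IBD
coefficients (1,0,0), (1/2,1/2,0), (3/4,1/4,0) and (7/8,1/8,0). Full
siblings of the true parent dominate the error budget; the others fall off
much faster with c.

## False negatives

`falseNegativeCurve()` uses plain Monte Carlo: observed genotypes of true
pairs are drawn per locus from the parent-offspring observed-pair
distribution, missing calls are drawn from the one-individual
missing-count chain *conditional on passing the cap* (forward recursion on
the count, exact backward placement across loci), and FNR(c) is the
fraction with MI count above `m` or LLR below `c`. False negatives are
reported but never drive threshold choice: the intended workflow minimises
the false-positive rate and takes the (typically small) false-negative
rate into account during interpretation.

## Experiment-wide error

Per-comparison rates accumulate across `Np x No` comparisons. The dominant
term uses the probability that a comparison pits the full sibling of the
true parent, `Pfs = 2 (mean full-sib family size - 1) / Np`; `Fp = Np * No
* alpha * Pfs` is the expected number of false assignments, and
`comprehensiveFP()` generalises to all four relationship categories. The
family-size list handed to `pfsEstimate()` should carry one entry per
candidate individual (so its plain mean is the size-biased mean an
offspring's parents see); the derivation assumes all evaluated offspring
descend from the candidates, so when residents contribute offspring the
estimate is biased high — a conservative direction for error control.
`selectThreshold()` returns the smallest grid threshold whose implied Fp
meets a user budget.

# Paired assignments and trio consistency

`assignParentPairs()` is deliberately simple plumbing so synthetic studies
run end to end without external trio software: a (dam, sire) pair is
accepted when both parents individually pass the two-step test and the trio
is Mendelian-consistent at all but at most `mTrio` loci, the best pair per
offspring by summed LLR being reported. The trio cap is *not* the pairwise
`m`: any of the six alleles in a trio can break compatibility, so true
trios show error-driven incompatibilities roughly an order of magnitude
more often than true pairs show opposing homozygotes. `trioMIThreshold()`
therefore rebuilds the cap from the Poisson-binomial distribution of
per-locus trio incompatibilities at the same exclusion bound. Sexes
constrain only which role a parent takes, never the acceptance itself.

# The synthetic-data generator

`simulatePopulation()` generates the study conditions the package is tested
under:

* **Panels**: biallelic loci with minor-allele frequencies uniform on
  0.05-0.5, `epsilon = 0.005`, per-locus missing rates uniform on
  0.01-0.03 (mean 2%, consistent with the ~97-98% per-locus genotyping
  success of amplicon panels); default L = 350.
* **Release scenarios**: `studyScenario("maleBiased")` releases 238 males
  and 108 females; `"nearEqual"` releases 977 males and 1094 females.
  Residents are unsampled; resident x resident matings (default 150/250)
  produce offspring that can receive no assignment, as a large fraction of
  real smolt samples does.
* **Sib structure among candidates** is generated, not assumed away,
  because close relatives are the method's whole error problem: released
  adults are drawn as offspring of virtual grandparent matings with
  family-size distributions chosen so that roughly 30% (male-biased
  scenario) or most (near-equal scenario) of candidates have a full
  sibling in the set, and consecutive families share a grandsire with
  probability 0.5/0.3 to create half-sib links.
* **Mating model**: each parent draws a strategy (assortative /
  disassortative / both). Females with an assortative slot mate one
  released male drawn from those offering assortative matings; a
  disassortative slot mates a fresh resident; "both" parents take one
  mating of each type. Offspring counts per mating are Poisson(3). This is
  the simplest model realising the three observable categories; it has no
  demographic realism (no survival, rearing-time or migration-year
  structure, no overlapping generations).
* **Phenotypes** (age, fork length in mm) are drawn from per-sex,
  per-strategy categorical/normal models whose means mirror the study's
  summary tables; they feed the demonstration t-tests only, never the
  inference.

Because the generator realises exactly the model the calibration assumes
(HWE, unlinked loci, independent errors and missingness), passing tests
show the machinery is *internally correct* — they cannot show robustness to
linked loci, allele-frequency misspecification, genotyping artefacts that
are not independent per allele, or inbred pedigrees, none of which the
model covers.

# Numerical choices

* Probability-conservation checks run at 1e-10 to 1e-12; forward
  recursions are plain sums of products, so error accumulation is benign
  at these scales.
* At `epsilon = 0` the parent-offspring likelihood of an incompatible pair
  is zero and the per-locus LLR is `-Inf` by convention; with any positive
  error rate all terms are finite.
* Backward sampling uses cumulative-sum inversion per locus; conditional
  distributions are renormalised before cumulation, and an all-zero MI
  conditional (possible at `epsilon = 0`) is never reachable because the
  corresponding event probability is zero. Requesting an empty stratum is
  an error rather than a silent empty draw.
* Ties at the acceptance boundary are kept: acceptance is `llr >= c`,
  matching the threshold-at-or-above rule.
* QC exclusion (missing fraction above `maxMissFrac`, default 0.10)
  applies per sample before any comparison, not per pair.
* All randomness flows through R's RNG, so `set.seed()` (or a function's
  `seed` argument, or `runConfig(seed = )`) makes every result, including
  the C++ samplers, bit-reproducible.

# Problem sizes used in the checks

The shipped tests and the acceptance script run at sizes chosen to make
Monte Carlo agreement checks decisive while staying desk-sized: exhaustive
enumeration oracles on 1-3 locus panels; stratified-versus-naive
equivalence on a 30-locus panel with 1e6 naive pairs; the exclusion-bound
check on a 350-locus panel with 1e6 error-free true pairs; and the
end-to-end recovery run at the full male-biased scenario (346 released
adults, ~1100-1500 sampled offspring, 350 loci) with 5000 draws per stratum
and 5000 false-negative simulations.

# Limitations

Beyond the generator's idealisations listed above: locus-specific error
rates are not estimated from data (one panel-wide `epsilon` is assumed);
genotype-likelihood input is not supported (calls are hard); grandparentage
and sibship reconstruction are out of scope; and the paired-parent helper
is a convenience, not a replacement for dedicated trio-assignment software
with FDR control. Uncertainty in the estimated allele frequencies and
missing rates is not propagated — they are treated as known, which is
reasonable for hundreds of genotyped candidates but optimistic for very
small parent samples.
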