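Package: soloParentage
Title: Single-Parent Parentage Assignment with Calibrated Error Rates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-parent parentage assignment for SNP panels when one
    parent of each offspring may be unsampled. Candidate parent-offspring
    pairs are screened by a Mendelian-incompatibility (MI) count threshold
    derived from the forward algorithm of a Markov chain over MI and
    missing-genotype events, then accepted by a log-likelihood ratio
    (parent-offspring versus unrelated) that marginalises true genotypes
    over a per-allele genotyping-error model. Per-comparison false-positive
    rates for unrelated individuals and for close relatives of the true
    parent (aunt/uncle, half-aunt/uncle, first cousin of parent) are
    estimated by stratified Monte Carlo with backward sampling of genotype
    pairs within MI strata; false-negative rates by direct Monte Carlo.
    Experiment-wide expected false positives combine per-comparison rates
    with the probability that a comparison involves a full sibling of the
    true parent. Includes a pedigreed-population simulator (full-sib and
    half-sib structure among candidate parents, unsampled resident
    spawners, two release scenarios) and mating-pattern classification of
    parents into assortative, disassortative or mixed strategies with the
    associated two-proportion z and pooled t statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'panel-model.R'
    'mi-engine.R'
    'assigner.R'
    'calibration.R'
    'io.R'
    'mating.R'
    'sim.R'
    'pipeline.R'
    'soloParentage-package.R'
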