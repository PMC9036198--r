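#' @include calibration.R assigner.R sim.R mating.R io.R
NULL

#' Build a run configuration
#'
#' Defaults follow the study settings: per-allele error 0.005, 10\% per-sample
#' missing-data cap, exclusion bound 1e-4 for the MI threshold, and an LLR
#' threshold grid of 0..20 (natural-log scale).
#'
#' @param ... overrides for any field: \code{parents}, \code{offspring},
#'   \code{panel} (input paths), or \code{scenario} (a [studyScenario()] to
#'   simulate inputs instead); \code{sex} (named vector for paired
#'   assignment, taken from the simulation when absent); \code{epsilon},
#'   \code{maxMissFrac}, \code{exclusionBound}, \code{cGrid},
#'   \code{nPerStratum}, \code{nFnrSims}, \code{relationships},
#'   \code{familySizes}, \code{fpBudget}, \code{seed}, \code{outDir}.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
  base <- list(
    parents = NULL, offspring = NULL, panel = NULL, scenario = NULL,
    sex = NULL, familySizes = NULL,
    epsilon = 0.005, maxMissFrac = 0.10, exclusionBound = 1e-4,
    cGrid = 0:20, nPerStratum = 10000, nFnrSims = 10000,
    relationships = c("UNRELATED", "AUNT_UNCLE", "HALF_AUNT_UNCLE",
                      "COUSIN_OF_PARENT"),
    fpBudget = 5, seed = 1, outDir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  structure(base, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [runConfig()] fields.
#' @return A list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$cGrid)) vals$cGrid <- as.numeric(vals$cGrid)
  if (!is.null(vals$scenario) && is.character(vals$scenario))
    vals$scenario <- studyScenario(vals$scenario)
  do.call(runConfig, vals)
}

.logLine <- function(log, ...) {
  line <- paste0(...)
  message(line)
  c(log, line)
}

#' Run the full single-parentage workflow
#'
#' Orchestrates the whole analysis: load (or simulate and corrupt) genotype
#' inputs, estimate allele frequencies and missing rates, compute the MI
#' threshold \code{m}, estimate false-positive curves per relationship and
#' the false-negative curve, select the LLR threshold \code{c} against the
#' experiment-wide false-positive budget, run single-parent (and, when
#' sexes are known, paired-parent) assignment, and classify parents into
#' mating-strategy categories.  All randomness flows from
#' \code{config$seed}.  When \code{config$outDir} is set, writes
#' \code{panel.tsv}, \code{curves.tsv}, \code{fnr.tsv},
#' \code{assignments.tsv}, \code{paired.tsv}, \code{strategies.tsv} and
#' \code{run_log.txt} there.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list: \code{panel}, \code{m}, \code{criteria},
#'   \code{curves}, \code{fnr}, \code{threshold}, \code{assignments},
#'   \code{paired}, \code{strategies}, \code{Pfs}, \code{Fp},
#'   \code{study} (when simulated), and the \code{log}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  log <- character()
  sex <- config$sex
  familySizes <- config$familySizes
  study <- NULL
  if (!is.null(config$scenario)) {
    log <- .logLine(log, "simulating study scenario '",
                    config$scenario$name, "'")
    panel <- simulatePanel(epsilon = config$epsilon)
    study <- simulatePopulation(panel, config$scenario)
    parentsObs <- corruptGenotypes(study$parents, panel)
    offspringObs <- corruptGenotypes(study$offspring, panel)
    sex <- stats::setNames(study$metadata$sex, study$metadata$id)
    familySizes <- study$familySizes
  } else {
    if (is.null(config$parents) || is.null(config$offspring) ||
        is.null(config$panel))
      stop("missing input: parents, offspring and panel paths are required")
    for (p in c(config$parents, config$offspring, config$panel))
      if (!file.exists(p)) stop("missing input file: ", p)
    panel <- readPanel(config$panel)
    parentsObs <- readGenotypes(config$parents, panel, config$maxMissFrac)
    offspringObs <- readGenotypes(config$offspring, panel,
                                  config$maxMissFrac)
  }
  ## locus-level model: frequencies from parents, missing rates pooled
  panel <- estimateAlleleFreqs(parentsObs, panel)
  panel <- estimateMissingRates(parentsObs, offspringObs, panel)
  L <- nLoci(panel)
  m <- miThreshold(panel, config$exclusionBound)
  U <- floor(config$maxMissFrac * L)
  log <- .logLine(log, "panel: ", L, " loci; m = ", m, " (P(exclude true pair) = ",
                  format(attr(m, "exclusionProb"), digits = 3),
                  "); U = ", U)
  tables <- .panelTables(panel)
  curves <- list()
  for (rel in config$relationships) {
    strat <- stratumSizes(panel, rel, m, config$maxMissFrac,
                          keepSlices = TRUE, tables = tables)
    log <- .logLine(log, rel, " stratum sizes: ",
                    paste(format(strat@p, digits = 3), collapse = " "))
    curves[[rel]] <- falsePositiveCurve(panel, rel, m, config$cGrid,
                                        config$nPerStratum,
                                        config$maxMissFrac,
                                        tables = tables, strat = strat)
  }
  curves <- do.call(rbind, curves)
  fnr <- falseNegativeCurve(panel, m, config$cGrid, config$nFnrSims,
                            config$maxMissFrac, tables = tables)
  Np <- nIndividuals(parentsObs)
  No <- nIndividuals(offspringObs)
  Pfs <- if (!is.null(familySizes)) pfsEstimate(familySizes, Np) else NA_real_
  auCurve <- curves[curves$relationship == "AUNT_UNCLE", , drop = FALSE]
  if (nrow(auCurve) == 0L)
    auCurve <- curves[curves$relationship == config$relationships[1], ,
                      drop = FALSE]
  sel <- if (!is.na(Pfs))
    selectThreshold(auCurve, Np, No, Pfs, config$fpBudget, fnr)
  else list(c = max(config$cGrid),
            alpha = auCurve$alpha[which.max(auCurve$c)], Fp = NA_real_,
            fnr = fnr$fnr[which.max(fnr$c)])
  log <- .logLine(log, "selected c = ", sel$c, "; alpha = ",
                  format(sel$alpha, digits = 3), "; Pfs = ",
                  format(Pfs, digits = 3), "; expected Fp = ",
                  format(sel$Fp, digits = 3), "; FNR = ",
                  format(sel$fnr, digits = 3))
  criteria <- assignmentCriteria(m, sel$c, config$maxMissFrac,
                                 config$exclusionBound)
  assignments <- assignSingleParents(parentsObs, offspringObs, panel,
                                     criteria)
  accepted <- assignments[assignments$accepted, , drop = FALSE]
  log <- .logLine(log, nrow(accepted), " accepted single-parent assignments (",
                  sum(accepted$multiple_flag), " flagged multiple)")
  paired <- NULL
  strategies <- NULL
  if (!is.null(sex)) {
    paired <- assignParentPairs(parentsObs, offspringObs, panel, criteria,
                                sex, single = assignments)
    log <- .logLine(log, nrow(paired), " paired-parent assignments")
    ## single-only records: offspring not resolved as a pair
    singleOnly <- accepted[!accepted$offspring_id %in% paired$offspring_id, ,
                           drop = FALSE]
    md <- data.frame(id = names(sex), sex = unname(sex))
    strategies <- classifyStrategies(paired, singleOnly, md)
  }
  res <- list(panel = panel, m = m, criteria = criteria, curves = curves,
              fnr = fnr, threshold = sel, assignments = assignments,
              paired = paired, strategies = strategies, Np = Np, No = No,
              Pfs = Pfs, Fp = sel$Fp, study = study, log = log)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(obj, f) utils::write.table(
      obj, file.path(config$outDir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writePanel(panel, file.path(config$outDir, "panel.tsv"))
    wp(curves, "curves.tsv")
    wp(fnr, "fnr.tsv")
    wp(assignments, "assignments.tsv")
    if (!is.null(paired)) wp(paired, "paired.tsv")
    if (!is.null(strategies)) wp(strategies$summary, "strategies.tsv")
    writeLines(log, file.path(config$outDir, "run_log.txt"))
  }
  invisible(res)
}
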