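#' @include AllClasses.R
NULL

#' Write a genotype table as delimited text
#'
#' Wide two-columns-per-locus layout: header \code{Ind}, \code{Pop}, then
#' \code{<locus>.A1}, \code{<locus>.A2} per locus with allele labels;
#' missing calls are written as \code{0} in both columns.
#'
#' @param gt a [GenotypeTable-class].
#' @param path output file path.
#' @param panel a [SnpPanel-class] supplying allele labels.
#' @param sep field separator (default tab).
#' @return Invisibly, the path.
#' @export
writeGenotypes <- function(gt, path, panel, sep = "\t") {
  L <- nLoci(panel)
  out <- data.frame(Ind = gt@individuals, Pop = gt@pop)
  for (l in seq_len(L)) {
    al <- panel@alleles[[l]]
    c1 <- ifelse(is.na(gt@a1[, l]), "0", al[gt@a1[, l]])
    c2 <- ifelse(is.na(gt@a2[, l]), "0", al[gt@a2[, l]])
    out[[paste0(panel@ids[l], ".A1")]] <- c1
    out[[paste0(panel@ids[l], ".A2")]] <- c2
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table from delimited text
#'
#' Expects the layout written by [writeGenotypes()]: columns \code{Ind},
#' \code{Pop}, then two columns per panel locus.  \code{0} or an empty
#' field in both allele columns marks a missing call.  Samples whose
#' missing fraction exceeds \code{maxMissFrac} are kept but flagged (their
#' ids are attached as attribute \code{"flagged"} and a message reports the
#' count); exclusion happens at assignment time.
#'
#' @param path input file path.
#' @param panel a [SnpPanel-class] declaring loci and alleles.
#' @param maxMissFrac per-sample missing-data cap used for flagging.
#' @param sep field separator (default tab).
#' @return A [GenotypeTable-class].
#' @export
readGenotypes <- function(path, panel, maxMissFrac = 0.10, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  L <- nLoci(panel)
  if (ncol(df) != 2L + 2L * L)
    stop("format error: expected ", 2L + 2L * L, " columns (Ind, Pop, two ",
         "per locus), found ", ncol(df))
  want <- c("Ind", "Pop",
            as.vector(rbind(paste0(panel@ids, ".A1"),
                            paste0(panel@ids, ".A2"))))
  if (!identical(names(df), want))
    stop("format error: column names do not match the panel loci")
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    al <- panel@alleles[[l]]
    for (side in 1:2) {
      v <- df[[2L + 2L * (l - 1L) + side]]
      miss <- v == "0" | v == ""
      idx <- match(v, al)
      bad <- which(is.na(idx) & !miss)
      if (length(bad))
        stop("parse error at locus ", panel@ids[l], ", row ", bad[1],
             ": unknown allele label '", v[bad[1]], "'")
      idx[miss] <- NA_integer_
      if (side == 1L) a1[, l] <- idx else a2[, l] <- idx
    }
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  gt <- GenotypeTable(a1, a2, individuals = df$Ind, pop = df$Pop,
                      lociIds = panel)
  mf <- missingFraction(gt)
  flagged <- names(mf)[mf > maxMissFrac]
  if (length(flagged))
    message(length(flagged), " sample(s) exceed the ", maxMissFrac,
            " missing-data cap and are flagged")
  attr(gt, "flagged") <- flagged
  gt
}

#' Write / read a SnpPanel as delimited text
#'
#' One row per locus: \code{id}, comma-joined \code{alleles}, comma-joined
#' \code{freqs}, \code{epsilon}, \code{missRate}.
#'
#' @param panel a [SnpPanel-class].
#' @param path file path.
#' @return \code{writePanel}: invisibly, the path. \code{readPanel}: a
#'   [SnpPanel-class].
#' @export
writePanel <- function(panel, path) {
  df <- data.frame(
    id = panel@ids,
    alleles = vapply(panel@alleles, paste, "", collapse = ","),
    freqs = vapply(panel@freqs, function(f)
      paste(sprintf("%.17g", f), collapse = ","), ""),
    epsilon = sprintf("%.17g", panel@epsilon),
    missRate = sprintf("%.17g", panel@missRate))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a stratum distribution as delimited text
#'
#' One row per stratum (\code{stratum}, \code{size}, \code{relationship}),
#' plus a final row for the lumped excluded mass.
#'
#' @param strat a [StratumDistribution-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeStrata <- function(strat, path) {
  stopifnot(is(strat, "StratumDistribution"))
  df <- data.frame(stratum = c(seq_along(strat@p) - 1L, NA),
                   size = c(strat@p, strat@excludedMass),
                   relationship = strat@relationship)
  df$stratum <- c(as.character(df$stratum[-nrow(df)]), "excluded")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  SnpPanel(df$id,
           alleles = lapply(strsplit(df$alleles, ","), trimws),
           freqs = lapply(strsplit(df$freqs, ","), as.numeric),
           epsilon = as.numeric(df$epsilon),
           missRate = as.numeric(df$missRate))
}
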