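#' @include AllClasses.R
NULL

#' Classify parents into mating-strategy categories
#'
#' A parent detected only in paired-parent assignments mated assortatively
#' (both parents were sampled, released adults); a parent detected only in
#' single-parent assignments mated disassortatively (its mate was an
#' unsampled resident); a parent detected in both kinds participated in both
#' strategies; a parent detected in neither was not reproductively
#' successful ("none").  Proportions are computed within successful parents
#' of each sex (and release year, when supplied).
#'
#' @param paired data.frame of paired-parent assignments with columns
#'   \code{offspring_id}, \code{dam_id}, \code{sire_id} (the
#'   [assignParentPairs()] output or an external trio-assignment table).
#' @param single data.frame of accepted single-parent assignments with
#'   columns \code{offspring_id} and \code{candidate_id} (or
#'   \code{parent_id}).
#' @param metadata data.frame with one row per candidate parent: \code{id},
#'   \code{sex}, optional \code{year}.
#' @return A list of class \code{"StrategySummary"}: \code{perParent}
#'   (\code{id}, \code{sex}, [\code{year},] \code{category}) and
#'   \code{summary} (counts and proportions of each category within
#'   successful parents, by sex [and year]).
#' @export
classifyStrategies <- function(paired, single, metadata) {
  pid <- if ("candidate_id" %in% names(single)) single$candidate_id
         else single$parent_id
  inPaired <- unique(c(paired$dam_id, paired$sire_id))
  inSingle <- unique(pid)
  known <- metadata$id
  stray <- setdiff(c(inPaired, inSingle), known)
  if (length(stray))
    stop("assignment tables reference unknown parent id(s): ",
         paste(utils::head(stray, 5), collapse = ", "))
  category <- ifelse(known %in% inPaired & known %in% inSingle, "both",
              ifelse(known %in% inPaired, "assortative",
              ifelse(known %in% inSingle, "disassortative", "none")))
  perParent <- data.frame(id = known, sex = metadata$sex,
                          category = category)
  byCols <- "sex"
  if ("year" %in% names(metadata)) {
    perParent$year <- metadata$year
    byCols <- c("year", "sex")
    perParent <- perParent[, c("id", "sex", "year", "category")]
  }
  lev <- c("assortative", "disassortative", "both")
  grp <- interaction(perParent[byCols], drop = FALSE, sep = "|")
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    sub <- perParent[grp == g, , drop = FALSE]
    succ <- sub[sub$category != "none", , drop = FALSE]
    cnt <- vapply(lev, function(cc) sum(succ$category == cc), integer(1))
    keys <- strsplit(g, "|", fixed = TRUE)[[1]]
    out <- as.data.frame(as.list(stats::setNames(keys, byCols)))
    out$n <- nrow(sub)
    out$n_successful <- nrow(succ)
    out$prop_successful <- nrow(succ) / max(nrow(sub), 1L)
    for (cc in lev) {
      out[[cc]] <- cnt[[cc]]
      out[[paste0("prop_", cc)]] <- cnt[[cc]] / max(nrow(succ), 1L)
    }
    out
  }))
  structure(list(perParent = perParent, summary = summ),
            class = "StrategySummary")
}

#' @export
print.StrategySummary <- function(x, ...) {
  cat("StrategySummary over", nrow(x$perParent), "parents\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pooled two-proportion z statistic
#'
#' \code{z = (x2/n2 - x1/n1) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))} with
#' \code{pbar = (x1 + x2) / (n1 + n2)}; no continuity correction.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return Numeric z.
#' @examples
#' twoProportionZ(30, 51, 3, 306)   # about -13.2
#' @export
twoProportionZ <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1)
    stop("undefined statistic: pooled proportion is 0 or 1")
  (x2 / n2 - x1 / n1) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
}

#' Two-sample t statistic from summary statistics
#'
#' Student's pooled-variance two-sample t (default) or Welch's t from group
#' means, standard deviations and sizes; \code{t = (mean1 - mean2) / SE}.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param welch use Welch's unequal-variance form (default FALSE).
#' @return Numeric t with attribute \code{"df"}.
#' @examples
#' abs(pooledT(3.07, 0.26, 28, 3.9, 0.7, 21))  # about 5.8
#' @export
pooledT <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stop("undefined statistic: zero variance and equal means")
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  structure((mean1 - mean2) / se, df = df)
}

#' Phenotype summaries by mating-strategy category
#'
#' Counts and mean fork length per category x age, plus per-category overall
#' mean age and fork length, for reproductively successful parents.
#' Parents without a phenotype record (missing fork length or age) are
#' excluded with a message; the number excluded is attached as attribute
#' \code{"nExcluded"}.
#'
#' @param classification a [classifyStrategies()] result (or its
#'   \code{perParent} data.frame).
#' @param phenotypes data.frame with \code{id}, \code{age}, \code{forkLength}.
#' @return data.frame with \code{category}, \code{age}, \code{n},
#'   \code{mean_fl}, and per-category overall rows (\code{age = NA}) giving
#'   \code{mean_age} and \code{mean_fl}.
#' @export
summarizePhenotypes <- function(classification, phenotypes) {
  per <- if (inherits(classification, "StrategySummary"))
    classification$perParent else classification
  succ <- per[per$category != "none", , drop = FALSE]
  ph <- phenotypes[match(succ$id, phenotypes$id), , drop = FALSE]
  ok <- !is.na(ph$age) & !is.na(ph$forkLength)
  nExcluded <- sum(!ok)
  if (nExcluded > 0)
    message(nExcluded, " parent(s) without phenotype records excluded")
  succ <- succ[ok, , drop = FALSE]; ph <- ph[ok, , drop = FALSE]
  rows <- list()
  for (cc in unique(succ$category)) {
    sel <- succ$category == cc
    for (a in sort(unique(ph$age[sel]))) {
      s2 <- sel & ph$age == a
      rows[[length(rows) + 1L]] <- data.frame(
        category = cc, age = a, n = sum(s2),
        mean_age = NA_real_, mean_fl = mean(ph$forkLength[s2]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      category = cc, age = NA_integer_, n = sum(sel),
      mean_age = mean(ph$age[sel]), mean_fl = mean(ph$forkLength[sel]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, nExcluded = nExcluded)
}
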