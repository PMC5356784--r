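# Cohort-level analysis of duplication calls against diagnosis and the rest
# of the MAP-kinase pathway (BRAF V600E, FGFR1 point mutations).

DIAGNOSES <- c("DNT", "PTO", "PDA", "GG", "PA")

#' Classify an FGFR1 mutation annotation
#'
#' Parses free-text mutation fields of the cohort table into
#' \code{"non_mutated"}, \code{"silent"}, \code{"missense"} or \code{NA}.
#' Single-letter protein annotations (e.g. \code{G539R}) are silent when the
#' reference and alternate residues agree (\code{L548L}, \code{L644L}) and
#' missense otherwise; silent changes are not activating and never count as
#' an FGFR1 alteration.
#'
#' @param x character vector of mutation annotations.
#' @return Character vector of classes (\code{NA} where the input is
#'   missing).
#' @examples
#' classifyMutation(c("G539R", "L548L", "Non-mutated", NA))
#' @export
classifyMutation <- function(x) {
  out <- rep(NA_character_, length(x))
  known <- !is.na(x)
  x2 <- trimws(x[known])
  cls <- rep("missense", length(x2))
  cls[tolower(x2) %in% c("non-mutated", "non_mutated", "wt")] <- "non_mutated"
  m <- regmatches(x2, regexec("^([A-Z])([0-9]+)([A-Z*])$", x2))
  aa <- vapply(m, function(g) if (length(g) == 4L && g[2L] == g[4L])
    "silent" else "", character(1))
  cls[aa == "silent"] <- "silent"
  bad <- cls == "missense" & !grepl("^[A-Z][0-9]+[A-Z*]$", x2)
  if (any(bad))
    stop("unparseable mutation annotation: ",
         paste(unique(x2[bad]), collapse = ", "))
  out[known] <- cls
  out
}

#' Load a cohort sample table
#'
#' Reads a CSV in the cohort schema (one row per patient with diagnosis,
#' BRAF status, FGFR1 duplication call, p-FGFR1 immunohistochemistry and
#' exon 12/14 mutation fields), validates the closed enumerations naming the
#' offending row and column on failure, and derives mutation classes for
#' the exon columns.  With \code{path = NULL} the packaged transcription of
#' the 36-patient study table is loaded.
#'
#' @param path CSV path, or \code{NULL} for the packaged cohort table.
#' @return A data.frame with the validated cohort columns plus
#'   \code{fgfr1_exon12_class} and \code{fgfr1_exon14_class}.
#' @examples
#' coh <- loadCohort()
#' table(coh$diagnosis)
#' @seealso [summarizeCohort()], [associationTest()]
#' @export
loadCohort <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_cohort.csv",
                        package = "dropletCNV", mustWork = TRUE)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "NA", comment.char = "#")
  need <- c("sample_id", "diagnosis", "braf_status", "fgfr1_duplication",
            "ihc_pfgfr1", "fgfr1_exon12", "fgfr1_exon14")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("cohort table is empty")

  checkEnum <- function(col, allowed, allowNA = TRUE) {
    v <- df[[col]]
    bad <- if (allowNA) !is.na(v) & !v %in% allowed else !v %in% allowed
    if (any(bad))
      stop(sprintf("unknown value '%s' in column '%s' (row %d)",
                   v[bad][1L], col, which(bad)[1L]))
  }
  checkEnum("diagnosis", DIAGNOSES, allowNA = FALSE)
  checkEnum("braf_status", c("V600E", "Non-mutated"))
  checkEnum("fgfr1_duplication", c("Yes", "No", "Inconclusive"),
            allowNA = FALSE)
  checkEnum("ihc_pfgfr1", c("Positive", "Negative", "+/-"))
  df$fgfr1_exon12_class <- classifyMutation(df$fgfr1_exon12)
  df$fgfr1_exon14_class <- classifyMutation(df$fgfr1_exon14)
  df
}

# An FGFR1 alteration = duplication or missense point mutation in either
# sequenced exon; silent changes excluded.
hasFgfr1Alteration <- function(records) {
  dup <- records$fgfr1_duplication == "Yes"
  mis <- records$fgfr1_exon12_class %in% "missense" |
         records$fgfr1_exon14_class %in% "missense"
  dup | mis
}

#' Summarize duplication and MAPK-pathway alterations of a cohort
#'
#' Computes the deterministic cohort counts: per-diagnosis duplication
#' counts and percentages (inconclusive calls excluded from the yes/no
#' denominator), BRAF V600E carriers, FGFR1 missense carriers, the
#' per-diagnosis MAPK-altered fraction (BRAF V600E or any FGFR1 alteration,
#' over all samples of the diagnosis), and the number of samples carrying
#' both a BRAF V600E mutation and an FGFR1 alteration (0 means the two are
#' mutually exclusive).
#'
#' @param records cohort data.frame from [loadCohort()].
#' @return A [CohortSummary-class].
#' @examples
#' summarizeCohort(loadCohort())
#' @export
summarizeCohort <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort")
  dx <- factor(records$diagnosis, levels = DIAGNOSES)
  dup <- records$fgfr1_duplication
  byDx <- do.call(rbind, lapply(levels(dx), function(d) {
    sel <- dx == d
    conclusive <- sel & dup != "Inconclusive"
    data.frame(
      diagnosis = d, n = sum(sel),
      duplicated = sum(sel & dup == "Yes"),
      inconclusive = sum(sel & dup == "Inconclusive"),
      pct_duplicated = if (sum(sel)) 100 * sum(sel & dup == "Yes") /
        sum(sel) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  braf <- records$braf_status %in% "V600E"
  mis <- records$fgfr1_exon12_class %in% "missense" |
         records$fgfr1_exon14_class %in% "missense"
  alt <- hasFgfr1Alteration(records)
  mapk <- braf | alt
  mapkFrac <- vapply(levels(dx), function(d)
    mean(mapk[dx == d]), numeric(1))
  new("CohortSummary",
      nSamples = nrow(records),
      duplicationByDiagnosis = byDx,
      brafCount = sum(braf),
      missenseCarriers = records$sample_id[mis],
      mapkAlteredFraction = mapkFrac,
      exclusivityOverlap = sum(braf & alt))
}

#' Association between diagnosis and FGFR1 duplication status
#'
#' Builds the diagnosis x duplication contingency table and tests it:
#' Fisher's exact test (two-sided) for the 2x2 DNT-vs-rest grouping,
#' chi-square for the per-diagnosis r x 2 table.  Inconclusive duplication
#' calls are excluded from the table by default or counted as
#' non-duplicated with \code{callHandling = "as_negative"}.
#'
#' @param records cohort data.frame from [loadCohort()].
#' @param grouping \code{"dnt_vs_rest"} (2x2, Fisher) or
#'   \code{"by_diagnosis"} (r x 2, chi-square).
#' @param callHandling treatment of inconclusive calls.
#' @return A list with \code{table}, \code{method}, \code{statistic}
#'   (chi-square only) and \code{p.value}.
#' @examples
#' associationTest(loadCohort())
#' @export
associationTest <- function(records,
                            grouping = c("dnt_vs_rest", "by_diagnosis"),
                            callHandling = c("exclude_inconclusive",
                                             "as_negative")) {
  grouping <- match.arg(grouping)
  callHandling <- match.arg(callHandling)
  dup <- records$fgfr1_duplication
  if (callHandling == "exclude_inconclusive") {
    keep <- dup != "Inconclusive"
    records <- records[keep, , drop = FALSE]
    dup <- dup[keep]
  } else {
    dup[dup == "Inconclusive"] <- "No"
  }
  dupF <- factor(dup, levels = c("Yes", "No"))
  grp <- if (grouping == "dnt_vs_rest")
    factor(ifelse(records$diagnosis == "DNT", "DNT", "other"),
           levels = c("DNT", "other"))
  else
    factor(records$diagnosis, levels = DIAGNOSES)
  tab <- table(grp, dupF)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is empty\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  if (grouping == "dnt_vs_rest") {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    list(table = tab, method = "Fisher's exact test (two-sided)",
         statistic = NA_real_, p.value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab))
    list(table = tab, method = "Pearson chi-square test",
         statistic = unname(ht$statistic), p.value = ht$p.value)
  }
}
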