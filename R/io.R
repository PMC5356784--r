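# CSV round-tripping with provenance headers, and truth-aware run metrics.
#
# Pipeline CSVs carry `#`-prefixed provenance lines (package version, config
# echo) that plain CSV parsers skip via comment.char.  Doubles are written
# at 6 significant digits so a fixed seed and config reproduce identical
# bytes.

#' Read a droplet well-count table
#'
#' Reads \code{wells.csv} (columns \code{sample_id}, \code{well_id},
#' \code{channel}, \code{n_total}, \code{n_positive}; channel FAM or HEX,
#' aliases TARGET_FAM/REFERENCE_HEX accepted), skipping \code{#} provenance
#' lines, and validates counts row by row.
#'
#' @param path CSV path.
#' @return A validated wells data.frame.
#' @seealso [writePipelineCsv()], [quantifySamples()]
#' @export
readWells <- function(path) {
  if (!file.exists(path)) stop("wells file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) stop("empty wells table: ", path)
  validateWells(df)
}

#' Read any pipeline CSV, skipping provenance lines
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
readPipelineCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

configLines <- function(config) {
  if (is.null(config)) return(character(0))
  stopifnot(is(config, "RunConfig"))
  th <- config@thresholds
  sp <- config@dropletSpec
  c(sprintf("# thresholds.cnv_cutoff = %g", th@cnvCutoff),
    sprintf("# thresholds.cnv_min_cutoff = %g", th@cnvMinCutoff),
    sprintf("# thresholds.min_conc_copies_per_ul = %g", th@minConc),
    sprintf("# thresholds.deletion_flag_cnv_max = %g", th@deletionFlagCnvMax),
    sprintf("# thresholds.artefact_flag_cnv_max = %g", th@artefactFlagCnvMax),
    sprintf("# droplet_volume_nl = %g", sp@dropletVolumeNl),
    sprintf("# alpha = %g", config@alpha),
    sprintf("# cnv_ci_method = %s", config@cnvCiMethod),
    sprintf("# call_handling = %s", config@callHandling),
    if (length(config@seed)) sprintf("# seed = %d", config@seed))
}

#' Write a pipeline CSV with provenance header
#'
#' Writes a data.frame as CSV preceded by \code{#}-prefixed provenance
#' lines (package version and, when a [RunConfig-class] is given, every
#' configuration value).  Doubles are serialized at 6 significant digits so
#' identical runs produce identical bytes.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config optional [RunConfig-class] echoed into the header.
#' @return The path, invisibly.
#' @examples
#' sim <- simulateSample("S1", dropletsPerWell = 15000)
#' f <- tempfile(fileext = ".csv")
#' writePipelineCsv(quantifySamples(sim), f, runConfig())
#' readPipelineCsv(f)
#' @export
writePipelineCsv <- function(df, path, config = NULL) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dropletCNV %s",
            as.character(utils::packageVersion("dropletCNV"))),
    configLines(config)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare duplication calls against simulator ground truth
#'
#' Joins a calls table to a truth table on \code{sample_id} and computes
#' run metrics: the confusion matrix of expected versus observed status,
#' sensitivity and specificity of the duplicated call among conclusive
#' truth, and the inconclusive rate.  Without a truth table a descriptive
#' status breakdown is returned.
#'
#' @param calls data.frame from [callSamples()].
#' @param truth optional truth data.frame from [simulateCohort()].
#' @return A list of metrics, serializable with [writeMetricsJson()].
#' @examples
#' coh <- simulateCohort(seed = 1, dropletsPerWell = 15000)
#' m <- reportMetrics(callSamples(coh$wells), coh$truth)
#' m$sensitivity
#' @export
reportMetrics <- function(calls, truth = NULL) {
  counts <- as.list(table(factor(calls$status,
    levels = c("duplicated", "non_duplicated", "inconclusive"))))
  out <- list(
    n_samples = nrow(calls),
    status_counts = counts,
    inconclusive_rate = counts$inconclusive / nrow(calls)
  )
  if (is.null(truth)) return(out)
  orphanCalls <- setdiff(calls$sample_id, truth$sample_id)
  orphanTruth <- setdiff(truth$sample_id, calls$sample_id)
  if (length(orphanCalls) || length(orphanTruth))
    stop("sample_id mismatch between calls and truth; orphans: ",
         paste(c(orphanCalls, orphanTruth), collapse = ", "))
  m <- merge(calls, truth, by = "sample_id")
  isDup <- m$true_fraction > 0 & m$expected_call == "duplicated"
  isNeg <- m$true_fraction == 0 & m$expected_call == "non_duplicated"
  out$confusion <- as.matrix(table(expected = m$expected_call,
                                   called = m$status))
  out$sensitivity <- if (any(isDup))
    mean(m$status[isDup] == "duplicated") else NA_real_
  out$specificity <- if (any(isNeg))
    mean(m$status[isNeg] != "duplicated") else NA_real_
  out
}

#' Serialize run metrics to JSON
#'
#' @param metrics list from [reportMetrics()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMetricsJson <- function(metrics, path) {
  if (!is.null(metrics$confusion)) {
    cm <- metrics$confusion
    metrics$confusion <- list(expected = rownames(cm), called = colnames(cm),
                              counts = unname(apply(cm, 1, as.list)))
  }
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
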