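# CNV estimation from the two channel concentrations and the dual-threshold
# duplication-calling rule.

#' Copy-number value from target and reference quantifications
#'
#' Computes the diploid-normalized copy number
#' \eqn{CNV = 2 \, c_{target} / c_{reference}} and propagates the Poisson
#' uncertainty of both channels into CNVmin/CNVmax bounds.
#'
#' Two propagation methods are available:
#' \describe{
#'   \item{\code{log_delta} (default)}{independent-channel delta method on
#'     the log ratio, \eqn{var(\ln ratio) = var(\ln\hat\lambda_t) +
#'     var(\ln\hat\lambda_r)}, bounds
#'     \eqn{CNV \exp(\mp z_{1-\alpha/2}\sqrt{var})}.  Symmetric on the log
#'     scale and strictly positive.}
#'   \item{\code{bound_ratio}}{conservative ratio of opposite per-channel CI
#'     bounds, \eqn{CNV_{min} = 2\,c_t^{low}/c_r^{high}},
#'     \eqn{CNV_{max} = 2\,c_t^{high}/c_r^{low}}; always at least as wide as
#'     the delta-method interval.}
#' }
#'
#' The numeric method takes two plain concentrations (any common unit) and
#' returns a point estimate with zero-width bounds; it exists for threshold
#' arithmetic such as inverting the duplication cutoff into a
#' target/reference ratio.
#'
#' @param target,reference [ConcentrationEstimate-class] objects for the
#'   FAM (target) and HEX (reference) channels, or plain positive numerics.
#' @param ciMethod interval propagation method, see Details.
#' @return A [CnvEstimate-class].
#' @examples
#' t <- estimateConcentration(15000, 820, channel = "FAM")
#' r <- estimateConcentration(15000, 730, channel = "HEX")
#' computeCnv(t, r)
#' computeCnv(45, 40)        # ratio 1.125 -> CNV 2.25
#' @seealso [classify()], [tumorFraction()]
#' @export
setGeneric("computeCnv", function(target, reference, ...)
  standardGeneric("computeCnv"))

#' @rdname computeCnv
#' @param ... passed between methods.
setMethod("computeCnv",
  signature(target = "ConcentrationEstimate",
            reference = "ConcentrationEstimate"),
  function(target, reference,
           ciMethod = c("log_delta", "bound_ratio")) {
    ciMethod <- match.arg(ciMethod)
    if (target@saturated || reference@saturated)
      stop("saturated channel: CNV is undefined when all droplets are ",
           "positive; merge additional wells")
    if (reference@conc <= 0)
      stop("undefined ratio: reference concentration is zero")
    if (target@conc <= 0)
      stop("undefined ratio: target concentration is zero (CNV bounds ",
           "cannot be formed); inspect the flagged concentration estimate")
    if (target@alpha != reference@alpha)
      stop("channels were estimated at different alpha levels")
    ratio <- target@conc / reference@conc
    cnvHat <- 2 * ratio
    z <- stats::qnorm(1 - target@alpha / 2)
    if (ciMethod == "log_delta") {
      vLog <- lambdaVariance(target@nTotal, target@nPositive) /
                target@lambda^2 +
              lambdaVariance(reference@nTotal, reference@nPositive) /
                reference@lambda^2
      lo <- cnvHat * exp(-z * sqrt(vLog))
      hi <- cnvHat * exp(z * sqrt(vLog))
    } else {
      lo <- 2 * target@ciLow / reference@ciHigh
      hi <- 2 * target@ciHigh / reference@ciLow
    }
    sid <- if (!is.na(target@sampleId)) target@sampleId else
             reference@sampleId
    new("CnvEstimate", sampleId = sid, cnv = cnvHat, cnvMin = lo,
        cnvMax = hi, ratio = ratio, ciMethod = ciMethod)
  })

#' @rdname computeCnv
setMethod("computeCnv",
  signature(target = "numeric", reference = "numeric"),
  function(target, reference) {
    stopifnot(length(target) == 1L, length(reference) == 1L)
    if (reference <= 0) stop("undefined ratio: reference concentration <= 0")
    if (target <= 0) stop("undefined ratio: target concentration <= 0")
    ratio <- target / reference
    new("CnvEstimate", sampleId = NA_character_, cnv = 2 * ratio,
        cnvMin = 2 * ratio, cnvMax = 2 * ratio, ratio = ratio,
        ciMethod = "none")
  })

#' Apply the dual-threshold duplication-calling rule
#'
#' Deterministically maps a CNV estimate and the two channel concentrations
#' to a duplication call:
#' \enumerate{
#'   \item Conclusiveness: each channel must reach the concentration floor
#'     (default 5 copies/\eqn{\mu}l).  A channel below it yields status
#'     \code{inconclusive} with a \code{low_target_conc} /
#'     \code{low_reference_conc} flag — low-DNA FFPE samples cannot be
#'     scored either way.
#'   \item Duplication: \code{duplicated} requires both \code{cnv >
#'     cnvCutoff} (default 2.25) and \code{cnvMin > cnvMinCutoff} (default
#'     2), strict inequalities.  When exactly one cutoff is passed the call
#'     is \code{inconclusive} with a \code{borderline} flag (more material
#'     would be needed), never \code{non_duplicated}.
#'   \item Low-CNV flags (adequate concentration only): \code{cnvMax} below
#'     the deletion level (default 2) flags \code{possible_deletion};
#'     below the artefact level (default 1.5) additionally
#'     \code{low_cnv_artefact}.  Status stays \code{non_duplicated} — a low
#'     CNV with low DNA is never interpreted.
#' }
#'
#' @param cnvEst a [CnvEstimate-class], or \code{NULL} when no CNV could be
#'   computed (degenerate channel); with \code{NULL} the status is
#'   \code{inconclusive}.
#' @param target,reference the per-channel
#'   [ConcentrationEstimate-class] objects.
#' @param thresholds a [CallThresholds-class].
#' @return A [SampleCall-class].
#' @examples
#' t <- estimateConcentration(15000, 1060, channel = "FAM")
#' r <- estimateConcentration(15000, 730, channel = "HEX")
#' classify(computeCnv(t, r), t, r)
#' @seealso [callSamples()]
#' @export
classify <- function(cnvEst, target, reference,
                     thresholds = CallThresholds()) {
  stopifnot(is(target, "ConcentrationEstimate"),
            is(reference, "ConcentrationEstimate"),
            is(thresholds, "CallThresholds"))
  flags <- character(0)
  reasons <- character(0)
  sid <- if (!is.na(target@sampleId)) target@sampleId else
           reference@sampleId

  if (target@saturated || reference@saturated) {
    flags <- c(flags, "saturated_well")
    reasons <- c(reasons, "a channel is saturated (all droplets positive)")
  }
  lowT <- !target@saturated && target@conc < thresholds@minConc
  lowR <- !reference@saturated && reference@conc < thresholds@minConc
  if (lowT) {
    flags <- c(flags, "low_target_conc")
    reasons <- c(reasons, sprintf(
      "target concentration %.3g copies/ul below conclusiveness floor %.3g",
      target@conc, thresholds@minConc))
  }
  if (lowR) {
    flags <- c(flags, "low_reference_conc")
    reasons <- c(reasons, sprintf(
      "reference concentration %.3g copies/ul below conclusiveness floor %.3g",
      reference@conc, thresholds@minConc))
  }

  if (lowT || lowR || is.null(cnvEst) || any(flags == "saturated_well")) {
    if (is.null(cnvEst) && !lowT && !lowR &&
        !any(flags == "saturated_well"))
      reasons <- c(reasons, "no CNV estimate available")
    return(new("SampleCall", sampleId = sid, status = "inconclusive",
               flags = flags, reasons = reasons, cnv = cnvEst))
  }

  passCnv <- cnvEst@cnv > thresholds@cnvCutoff
  passMin <- cnvEst@cnvMin > thresholds@cnvMinCutoff
  if (passCnv && passMin) {
    status <- "duplicated"
    reasons <- c(reasons, sprintf(
      "CNV %.3f > %.3g and CNVmin %.3f > %.3g",
      cnvEst@cnv, thresholds@cnvCutoff, cnvEst@cnvMin,
      thresholds@cnvMinCutoff))
  } else if (passCnv != passMin) {
    status <- "inconclusive"
    flags <- c(flags, "borderline")
    reasons <- c(reasons, sprintf(
      "cutoffs disagree (CNV %.3f vs %.3g, CNVmin %.3f vs %.3g): more material needed",
      cnvEst@cnv, thresholds@cnvCutoff, cnvEst@cnvMin,
      thresholds@cnvMinCutoff))
  } else {
    status <- "non_duplicated"
    reasons <- c(reasons, sprintf(
      "CNV %.3f <= %.3g or CNVmin %.3f <= %.3g",
      cnvEst@cnv, thresholds@cnvCutoff, cnvEst@cnvMin,
      thresholds@cnvMinCutoff))
    if (cnvEst@cnvMax < thresholds@deletionFlagCnvMax) {
      flags <- c(flags, "possible_deletion")
      reasons <- c(reasons, sprintf(
        "CNVmax %.3f < %.3g at adequate concentration: possible deletion",
        cnvEst@cnvMax, thresholds@deletionFlagCnvMax))
    }
    if (cnvEst@cnvMax < thresholds@artefactFlagCnvMax) {
      flags <- c(flags, "low_cnv_artefact")
      reasons <- c(reasons, sprintf(
        "CNVmax %.3f < %.3g: likely technical artefact",
        cnvEst@cnvMax, thresholds@artefactFlagCnvMax))
    }
  }
  new("SampleCall", sampleId = sid, status = status, flags = flags,
      reasons = reasons, cnv = cnvEst)
}

#' Quantify and call every sample of a well table
#'
#' End-to-end pipeline step: merges replicate wells per channel, estimates
#' both channel concentrations, computes the CNV with propagated bounds and
#' applies the duplication-calling rule.  Samples whose CNV cannot be
#' computed (a zero-positive or saturated channel) are returned with
#' \code{NA} CNV fields and an inconclusive or flagged status instead of
#' aborting the run.
#'
#' @param wells data.frame in the wells schema (see [readWells()]); both
#'   channels must be present for every sample.
#' @param config a [RunConfig-class] bundling thresholds, droplet geometry,
#'   alpha and the CNV interval method.
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{cnv}, \code{cnv_min}, \code{cnv_max}, \code{ratio},
#'   \code{tumor_fraction}, \code{status}, \code{flags}
#'   (semicolon-separated).
#' @examples
#' sim <- simulateSample("S1", trueFraction = 1, referenceConc = 60)
#' callSamples(sim)
#' @seealso [quantifySamples()], [classify()]
#' @export
callSamples <- function(wells, config = runConfig()) {
  stopifnot(is(config, "RunConfig"))
  wells <- validateWells(wells)
  res <- lapply(split(wells, wells$sample_id), function(w) {
    sid <- w$sample_id[1L]
    have <- unique(w$channel)
    missing <- setdiff(unname(CHANNELS), have)
    if (length(missing))
      stop("sample ", sid, " is missing channel(s): ",
           paste(missing, collapse = ", "))
    ests <- lapply(unname(CHANNELS), function(ch) {
      m <- mergeWells(w[w$channel == ch, , drop = FALSE])
      estimateConcentration(m$n_total, m$n_positive,
                            spec = config@dropletSpec, alpha = config@alpha,
                            sampleId = sid, channel = ch,
                            nWells = m$n_wells)
    })
    names(ests) <- unname(CHANNELS)
    target <- ests[["FAM"]]; reference <- ests[["HEX"]]
    cnvEst <- if (target@saturated || reference@saturated ||
                  target@conc <= 0 || reference@conc <= 0) NULL else
      computeCnv(target, reference, ciMethod = config@cnvCiMethod)
    call <- classify(cnvEst, target, reference, config@thresholds)
    data.frame(
      sample_id = sid,
      cnv = if (is.null(cnvEst)) NA_real_ else cnvEst@cnv,
      cnv_min = if (is.null(cnvEst)) NA_real_ else cnvEst@cnvMin,
      cnv_max = if (is.null(cnvEst)) NA_real_ else cnvEst@cnvMax,
      ratio = if (is.null(cnvEst)) NA_real_ else cnvEst@ratio,
      tumor_fraction = if (is.null(cnvEst)) NA_real_ else
        tumorFraction(cnvEst),
      status = call@status,
      flags = paste(call@flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
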