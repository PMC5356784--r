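#' Droplet partition geometry of a ddPCR assay
#'
#' Describes the physical partitioning of one droplet digital PCR well:
#' the volume of a single droplet and the nominal number of accepted
#' droplets the instrument emulsifies per well.  Template concentration in
#' copies/\eqn{\mu}l is the mean copies-per-droplet \eqn{\lambda} divided by
#' the droplet volume expressed in \eqn{\mu}l, so every concentration
#' reported by the package scales with \code{dropletVolumeNl}.
#'
#' @slot dropletVolumeNl numeric(1), volume of one droplet in nanolitres.
#' @slot dropletsPerWell integer(1), nominal accepted-droplet count per well.
#'
#' @seealso [estimateConcentration()], [simulateWell()]
#' @export
setClass("DropletSpec",
  representation(
    dropletVolumeNl = "numeric",
    dropletsPerWell = "integer"
  ),
  prototype(dropletVolumeNl = 1.0, dropletsPerWell = 15000L),
  validity = function(object) {
    msg <- character()
    v <- object@dropletVolumeNl
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, "dropletVolumeNl must be a single positive finite number")
    n <- object@dropletsPerWell
    if (length(n) != 1L || is.na(n) || n < 1L)
      msg <- c(msg, "dropletsPerWell must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn DropletSpec-class Constructor.  Defaults describe the
#'   QX100-style emulsion used for the FGFR1 duplex assay: ~15,000 accepted
#'   droplets of ~1 nL each.
#' @param dropletVolumeNl droplet volume in nanolitres (default 1).
#' @param dropletsPerWell nominal accepted droplets per well (default 15000).
#' @return A \code{DropletSpec} object.
#' @examples
#' DropletSpec()
#' DropletSpec(dropletVolumeNl = 0.85)
#' @export
DropletSpec <- function(dropletVolumeNl = 1.0, dropletsPerWell = 15000L) {
  new("DropletSpec",
      dropletVolumeNl = as.numeric(dropletVolumeNl),
      dropletsPerWell = as.integer(dropletsPerWell))
}

#' Per-channel template concentration estimate with Poisson-based CI
#'
#' Result of Poisson absolute quantification of one fluorescence channel for
#' one sample (possibly after merging replicate wells): the estimated mean
#' copies per droplet \eqn{\hat\lambda = -\ln(n_{neg}/n_{tot})}, the implied
#' concentration in copies/\eqn{\mu}l, and a Poisson-based confidence
#' interval.  Degenerate wells (no positive droplets, or every droplet
#' positive) carry one-sided bounds and an explanatory flag instead of
#' failing, so that well merging can still rescue them.
#'
#' @slot sampleId character(1) sample identifier (may be \code{NA}).
#' @slot channel character(1), \code{"FAM"} (target) or \code{"HEX"}
#'   (reference).
#' @slot lambda numeric(1), estimated mean copies per droplet
#'   (\code{Inf} when saturated).
#' @slot conc numeric(1), concentration in copies/\eqn{\mu}l.
#' @slot ciLow,ciHigh numeric(1), confidence bounds in copies/\eqn{\mu}l.
#' @slot nTotal,nPositive integer(1), accepted and positive droplet counts
#'   the estimate is based on.
#' @slot nWells integer(1), number of wells merged into the counts.
#' @slot alpha numeric(1), significance level of the interval.
#' @slot dropletVolumeNl numeric(1), droplet volume used for the
#'   copies/\eqn{\mu}l conversion.
#' @slot saturated logical(1), \code{TRUE} when all droplets were positive.
#' @slot flags character vector of quality flags
#'   (\code{"saturated_well"}, \code{"zero_positive"}).
#'
#' @seealso [estimateConcentration()], [computeCnv()]
#' @export
setClass("ConcentrationEstimate",
  representation(
    sampleId = "character",
    channel = "character",
    lambda = "numeric",
    conc = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    nTotal = "integer",
    nPositive = "integer",
    nWells = "integer",
    alpha = "numeric",
    dropletVolumeNl = "numeric",
    saturated = "logical",
    flags = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nTotal < 1L)
      msg <- c(msg, "nTotal must be >= 1")
    if (object@nPositive < 0L || object@nPositive > object@nTotal)
      msg <- c(msg, "nPositive must satisfy 0 <= nPositive <= nTotal")
    if (!(object@alpha > 0 && object@alpha <= 1))
      msg <- c(msg, "alpha must be in (0, 1]")
    ok <- object@ciLow <= object@conc + 1e-12 &&
          object@conc <= object@ciHigh + 1e-12
    if (!object@saturated && !isTRUE(ok))
      msg <- c(msg, "confidence bounds must bracket the point estimate")
    if (any(c(object@ciLow, object@conc) < 0, na.rm = TRUE))
      msg <- c(msg, "concentration and bounds must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Copy-number estimate with propagated confidence bounds
#'
#' Diploid-normalized copy-number value of the target amplicon relative to
#' the reference amplicon, CNV = 2 x (target concentration / reference
#' concentration), together with CNVmin/CNVmax bounds obtained by
#' propagating the Poisson uncertainty of both channels
#' (see [computeCnv()] for the two propagation methods).
#'
#' @slot sampleId character(1) sample identifier (may be \code{NA}).
#' @slot cnv numeric(1), point estimate; 2 corresponds to a normal diploid
#'   locus.
#' @slot cnvMin,cnvMax numeric(1), lower/upper confidence bounds.
#' @slot ratio numeric(1), target/reference concentration ratio
#'   (\code{cnv/2}).
#' @slot ciMethod character(1), \code{"log_delta"}, \code{"bound_ratio"} or
#'   \code{"none"} (point estimate only, degenerate zero-width bounds).
#'
#' @seealso [computeCnv()], [tumorFraction()], [classify()]
#' @export
setClass("CnvEstimate",
  representation(
    sampleId = "character",
    cnv = "numeric",
    cnvMin = "numeric",
    cnvMax = "numeric",
    ratio = "numeric",
    ciMethod = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@cnv, 2 * object@ratio, tolerance = 1e-9)))
      msg <- c(msg, "cnv must equal 2 * ratio")
    if (!(object@cnvMin <= object@cnv + 1e-12 &&
          object@cnv <= object@cnvMax + 1e-12))
      msg <- c(msg, "bounds must satisfy cnvMin <= cnv <= cnvMax")
    if (any(c(object@cnv, object@cnvMin, object@cnvMax) <= 0))
      msg <- c(msg, "cnv and its bounds must be strictly positive")
    if (!object@ciMethod %in% c("log_delta", "bound_ratio", "none"))
      msg <- c(msg, "ciMethod must be 'log_delta', 'bound_ratio' or 'none'")
    if (length(msg)) msg else TRUE
  }
)

setClassUnion("CnvEstimateOrNULL", c("CnvEstimate", "NULL"))

#' Decision thresholds of the duplication-calling rule
#'
#' The dual-threshold rule calls a sample duplicated only when the CNV point
#' estimate exceeds \code{cnvCutoff} (default 2.25, i.e. a target/reference
#' ratio of 1.125, a monoallelic duplication in 25% of cells) AND its lower
#' bound CNVmin exceeds \code{cnvMinCutoff} (default 2, the diploid value).
#' Both channels must reach \code{minConc} copies/\eqn{\mu}l (default 5) for
#' a conclusive result.  Low CNVmax values are flagged: below
#' \code{deletionFlagCnvMax} (default 2) as a possible deletion, below
#' \code{artefactFlagCnvMax} (default 1.5) as a likely technical artefact.
#' All cutoffs are strict inequalities.
#'
#' @slot cnvCutoff numeric(1), duplication cutoff on the CNV point estimate.
#' @slot cnvMinCutoff numeric(1), duplication cutoff on CNVmin.
#' @slot minConc numeric(1), conclusiveness floor in copies/\eqn{\mu}l,
#'   applied to both channels.
#' @slot deletionFlagCnvMax numeric(1), CNVmax level below which a possible
#'   deletion is flagged (at adequate concentration).
#' @slot artefactFlagCnvMax numeric(1), CNVmax level below which a likely
#'   artefact is flagged.
#'
#' @seealso [classify()]
#' @export
setClass("CallThresholds",
  representation(
    cnvCutoff = "numeric",
    cnvMinCutoff = "numeric",
    minConc = "numeric",
    deletionFlagCnvMax = "numeric",
    artefactFlagCnvMax = "numeric"
  ),
  prototype(cnvCutoff = 2.25, cnvMinCutoff = 2.0, minConc = 5.0,
            deletionFlagCnvMax = 2.0, artefactFlagCnvMax = 1.5),
  validity = function(object) {
    msg <- character()
    if (!(object@cnvCutoff > object@cnvMinCutoff &&
          object@cnvMinCutoff > 0))
      msg <- c(msg, "must satisfy cnvCutoff > cnvMinCutoff > 0")
    if (object@minConc <= 0)
      msg <- c(msg, "minConc must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn CallThresholds-class Constructor with the published defaults.
#' @param cnvCutoff CNV duplication cutoff (default 2.25).
#' @param cnvMinCutoff CNVmin duplication cutoff (default 2).
#' @param minConc conclusiveness floor in copies/ul (default 5).
#' @param deletionFlagCnvMax CNVmax level flagging a possible deletion
#'   (default 2).
#' @param artefactFlagCnvMax CNVmax level flagging a likely artefact
#'   (default 1.5).
#' @return A \code{CallThresholds} object.
#' @examples
#' CallThresholds()
#' @export
CallThresholds <- function(cnvCutoff = 2.25, cnvMinCutoff = 2.0,
                           minConc = 5.0, deletionFlagCnvMax = 2.0,
                           artefactFlagCnvMax = 1.5) {
  new("CallThresholds", cnvCutoff = as.numeric(cnvCutoff),
      cnvMinCutoff = as.numeric(cnvMinCutoff), minConc = as.numeric(minConc),
      deletionFlagCnvMax = as.numeric(deletionFlagCnvMax),
      artefactFlagCnvMax = as.numeric(artefactFlagCnvMax))
}

#' Duplication call for one sample
#'
#' The outcome of applying the dual-threshold duplication rule to one
#' sample: a status (\code{duplicated}, \code{non_duplicated} or
#' \code{inconclusive}), machine-readable flags, and a human-readable audit
#' trail of the decisions taken.  A sample is inconclusive whenever either
#' channel is below the conclusiveness floor, or when the two duplication
#' cutoffs disagree (borderline).
#'
#' @slot sampleId character(1).
#' @slot status character(1), one of \code{"duplicated"},
#'   \code{"non_duplicated"}, \code{"inconclusive"}.
#' @slot flags character vector drawn from \code{low_target_conc},
#'   \code{low_reference_conc}, \code{borderline}, \code{possible_deletion},
#'   \code{low_cnv_artefact}, \code{saturated_well}.
#' @slot reasons character vector, audit trail.
#' @slot cnv the underlying [CnvEstimate-class], or \code{NULL} when no CNV
#'   could be computed (degenerate channel).
#'
#' @seealso [classify()], [callSamples()]
#' @export
setClass("SampleCall",
  representation(
    sampleId = "character",
    status = "character",
    flags = "character",
    reasons = "character",
    cnv = "CnvEstimateOrNULL"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@status %in% c("duplicated", "non_duplicated", "inconclusive"))
      msg <- c(msg, "unknown status")
    known <- c("low_target_conc", "low_reference_conc", "borderline",
               "possible_deletion", "low_cnv_artefact", "saturated_well")
    if (!all(object@flags %in% known))
      msg <- c(msg, "unknown flag value")
    concFlag <- any(object@flags %in% c("low_target_conc",
                                        "low_reference_conc"))
    if (concFlag && object@status != "inconclusive")
      msg <- c(msg, "low-concentration flags force an inconclusive status")
    if (length(msg)) msg else TRUE
  }
)

#' Cohort-level summary of duplication and MAPK-pathway alterations
#'
#' Deterministic counts computed from a cohort table: per-diagnosis
#' duplication counts and percentages, BRAF V600E carriers, FGFR1 missense
#' carriers, the per-diagnosis fraction of samples with any MAP-kinase
#' pathway alteration (BRAF V600E, FGFR1 duplication or FGFR1 missense
#' mutation), and the overlap between BRAF V600E and FGFR1 alterations
#' (0 = mutually exclusive).
#'
#' @slot nSamples integer(1), cohort size.
#' @slot duplicationByDiagnosis data.frame with columns \code{diagnosis},
#'   \code{n}, \code{duplicated}, \code{inconclusive}, \code{pct_duplicated}.
#' @slot brafCount integer(1), number of BRAF V600E carriers.
#' @slot missenseCarriers character vector of sample ids with an FGFR1
#'   missense mutation (silent changes excluded).
#' @slot mapkAlteredFraction named numeric, per-diagnosis fraction of
#'   MAPK-altered samples.
#' @slot exclusivityOverlap integer(1), samples carrying both BRAF V600E and
#'   an FGFR1 alteration.
#'
#' @seealso [summarizeCohort()]
#' @export
setClass("CohortSummary",
  representation(
    nSamples = "integer",
    duplicationByDiagnosis = "data.frame",
    brafCount = "integer",
    missenseCarriers = "character",
    mapkAlteredFraction = "numeric",
    exclusivityOverlap = "integer"
  )
)

#' Pipeline run configuration
#'
#' Bundles every tunable of the quantification-and-calling pipeline so a run
#' is reproducible from its configuration alone: thresholds, droplet
#' geometry, CI level, CNV interval propagation method, how inconclusive
#' calls enter association tests, and an optional RNG seed.
#'
#' @slot thresholds a [CallThresholds-class].
#' @slot dropletSpec a [DropletSpec-class].
#' @slot alpha numeric(1) in (0,1), CI significance level (default 0.05).
#' @slot cnvCiMethod \code{"log_delta"} or \code{"bound_ratio"}.
#' @slot callHandling \code{"exclude_inconclusive"} or \code{"as_negative"}.
#' @slot seed integer vector of length 0 or 1.
#'
#' @export
setClass("RunConfig",
  representation(
    thresholds = "CallThresholds",
    dropletSpec = "DropletSpec",
    alpha = "numeric",
    cnvCiMethod = "character",
    callHandling = "character",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@alpha > 0 && object@alpha < 1))
      msg <- c(msg, "alpha must be in (0, 1)")
    if (!object@cnvCiMethod %in% c("log_delta", "bound_ratio"))
      msg <- c(msg, "cnvCiMethod must be 'log_delta' or 'bound_ratio'")
    if (!object@callHandling %in% c("exclude_inconclusive", "as_negative"))
      msg <- c(msg, "callHandling must be 'exclude_inconclusive' or 'as_negative'")
    if (length(object@seed) > 1L)
      msg <- c(msg, "seed must have length 0 or 1")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn RunConfig-class Constructor.
#' @param thresholds a [CallThresholds-class] (defaults to the published
#'   cutoffs).
#' @param dropletSpec a [DropletSpec-class].
#' @param alpha CI significance level, default 0.05.
#' @param cnvCiMethod CNV interval propagation, \code{"log_delta"} (default)
#'   or \code{"bound_ratio"}.
#' @param callHandling treatment of inconclusive calls in association tests.
#' @param seed optional integer RNG seed.
#' @return A \code{RunConfig} object.
#' @examples
#' runConfig(alpha = 0.01)
#' @export
runConfig <- function(thresholds = CallThresholds(),
                      dropletSpec = DropletSpec(),
                      alpha = 0.05,
                      cnvCiMethod = c("log_delta", "bound_ratio"),
                      callHandling = c("exclude_inconclusive", "as_negative"),
                      seed = NULL) {
  new("RunConfig", thresholds = thresholds, dropletSpec = dropletSpec,
      alpha = as.numeric(alpha), cnvCiMethod = match.arg(cnvCiMethod),
      callHandling = match.arg(callHandling),
      seed = if (is.null(seed)) integer(0) else as.integer(seed))
}
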