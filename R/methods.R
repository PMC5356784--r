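# Accessors and show methods.

#' @rdname ConcentrationEstimate-class
setMethod("lambdaHat", "ConcentrationEstimate", function(object)
  object@lambda)

#' @rdname ConcentrationEstimate-class
setMethod("concentration", "ConcentrationEstimate", function(object)
  object@conc)

#' @rdname ConcentrationEstimate-class
setMethod("ciLow", "ConcentrationEstimate", function(object) object@ciLow)

#' @rdname ConcentrationEstimate-class
setMethod("ciHigh", "ConcentrationEstimate", function(object) object@ciHigh)

#' @rdname ConcentrationEstimate-class
setMethod("isSaturated", "ConcentrationEstimate", function(object)
  object@saturated)

#' @rdname ConcentrationEstimate-class
setMethod("sampleId", "ConcentrationEstimate", function(object)
  object@sampleId)

#' @rdname CnvEstimate-class
setMethod("cnv", "CnvEstimate", function(object) object@cnv)

#' @rdname CnvEstimate-class
setMethod("cnvMin", "CnvEstimate", function(object) object@cnvMin)

#' @rdname CnvEstimate-class
setMethod("cnvMax", "CnvEstimate", function(object) object@cnvMax)

#' @rdname CnvEstimate-class
setMethod("cnvRatio", "CnvEstimate", function(object) object@ratio)

#' @rdname CnvEstimate-class
setMethod("sampleId", "CnvEstimate", function(object) object@sampleId)

#' @rdname SampleCall-class
setMethod("callStatus", "SampleCall", function(object) object@status)

#' @rdname SampleCall-class
setMethod("callFlags", "SampleCall", function(object) object@flags)

#' @rdname SampleCall-class
setMethod("callReasons", "SampleCall", function(object) object@reasons)

#' @rdname SampleCall-class
setMethod("sampleId", "SampleCall", function(object) object@sampleId)

#' @rdname SampleCall-class
#' @param object a \code{SampleCall}.
setMethod("cnv", "SampleCall", function(object) object@cnv)

#' @rdname tumorFraction
setMethod("tumorFraction", "numeric", function(object)
  pmin(pmax(object - 2, 0), 1))

#' @rdname tumorFraction
setMethod("tumorFraction", "CnvEstimate", function(object)
  tumorFraction(object@cnv))

setMethod("show", "DropletSpec", function(object) {
  cat("DropletSpec:", object@dropletVolumeNl, "nL/droplet,",
      object@dropletsPerWell, "droplets/well (nominal)\n")
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat(sprintf(
    "ConcentrationEstimate [%s / %s]\n", object@sampleId, object@channel))
  cat(sprintf("  %d/%d positive droplets in %d well(s)\n",
              object@nPositive, object@nTotal, object@nWells))
  if (object@saturated) {
    cat(sprintf("  saturated: conc > %.2f copies/ul (one-sided %g%% bound)\n",
                object@ciLow, 100 * (1 - object@alpha)))
  } else {
    cat(sprintf("  lambda = %.6f copies/droplet\n", object@lambda))
    cat(sprintf("  conc   = %.2f copies/ul  [%.2f, %.2f] %g%% CI\n",
                object@conc, object@ciLow, object@ciHigh,
                100 * (1 - object@alpha)))
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CnvEstimate", function(object) {
  cat(sprintf("CnvEstimate [%s]\n", object@sampleId))
  cat(sprintf("  CNV = %.3f  [CNVmin %.3f, CNVmax %.3f] (%s)\n",
              object@cnv, object@cnvMin, object@cnvMax, object@ciMethod))
  cat(sprintf("  target/reference ratio = %.4f; implied duplicated-cell fraction = %.1f%%\n",
              object@ratio, 100 * tumorFraction(object)))
})

setMethod("show", "CallThresholds", function(object) {
  cat("CallThresholds: duplicated iff CNV >", object@cnvCutoff,
      "and CNVmin >", object@cnvMinCutoff, "\n")
  cat("  conclusiveness floor:", object@minConc, "copies/ul per channel\n")
  cat("  low-CNV flags: possible deletion if CNVmax <",
      object@deletionFlagCnvMax, "; artefact if CNVmax <",
      object@artefactFlagCnvMax, "\n")
})

setMethod("show", "SampleCall", function(object) {
  cat(sprintf("SampleCall [%s]: %s\n", object@sampleId, object@status))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  for (r in object@reasons) cat("  -", r, "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary of", object@nSamples, "samples\n")
  cat("  duplication by diagnosis:\n")
  df <- object@duplicationByDiagnosis
  for (i in seq_len(nrow(df)))
    cat(sprintf("    %-4s %d/%d duplicated (%.1f%%), %d inconclusive\n",
                df$diagnosis[i], df$duplicated[i], df$n[i],
                df$pct_duplicated[i], df$inconclusive[i]))
  cat("  BRAF V600E carriers:", object@brafCount, "\n")
  cat("  FGFR1 missense carriers:",
      if (length(object@missenseCarriers))
        paste(object@missenseCarriers, collapse = ", ") else "none", "\n")
  cat("  BRAF/FGFR1 alteration overlap:", object@exclusivityOverlap, "\n")
  mk <- object@mapkAlteredFraction
  cat("  MAPK-altered fraction:",
      paste(sprintf("%s %.1f%%", names(mk), 100 * mk), collapse = ", "),
      "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: alpha =", object@alpha, "| CNV CI =", object@cnvCiMethod,
      "| inconclusive handling =", object@callHandling, "\n")
  show(object@thresholds)
  show(object@dropletSpec)
})
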