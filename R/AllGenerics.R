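# Accessor generics. Slot access from user code goes through these.

#' @rdname ConcentrationEstimate-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))

#' @rdname ConcentrationEstimate-class
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))

#' @rdname ConcentrationEstimate-class
#' @export
setGeneric("ciLow", function(object) standardGeneric("ciLow"))

#' @rdname ConcentrationEstimate-class
#' @export
setGeneric("ciHigh", function(object) standardGeneric("ciHigh"))

#' @rdname ConcentrationEstimate-class
#' @export
setGeneric("isSaturated", function(object) standardGeneric("isSaturated"))

#' @rdname CnvEstimate-class
#' @export
setGeneric("cnv", function(object) standardGeneric("cnv"))

#' @rdname CnvEstimate-class
#' @export
setGeneric("cnvMin", function(object) standardGeneric("cnvMin"))

#' @rdname CnvEstimate-class
#' @export
setGeneric("cnvMax", function(object) standardGeneric("cnvMax"))

#' @rdname CnvEstimate-class
#' @export
setGeneric("cnvRatio", function(object) standardGeneric("cnvRatio"))

#' @rdname SampleCall-class
#' @export
setGeneric("callStatus", function(object) standardGeneric("callStatus"))

#' @rdname SampleCall-class
#' @export
setGeneric("callFlags", function(object) standardGeneric("callFlags"))

#' @rdname SampleCall-class
#' @export
setGeneric("callReasons", function(object) standardGeneric("callReasons"))

#' @rdname SampleCall-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' Duplicated-cell fraction implied by a CNV value
#'
#' Inverts the monoallelic-duplication mixture model.  If a fraction
#' \eqn{f} of cells carries one extra copy of the target region, cells
#' average \eqn{2 + f} target copies against 2 reference copies, so the
#' diploid-normalized copy number is \eqn{CNV = 2 + f} and
#' \eqn{f = clamp(CNV - 2, 0, 1)}.  A CNV of 2.25 therefore corresponds to
#' a monoallelic duplication in 25% of the analyzed cells.
#'
#' @param object a [CnvEstimate-class] or a numeric vector of CNV values.
#' @return Numeric duplicated-cell fraction in \[0, 1\].
#' @examples
#' tumorFraction(2.25)
#' tumorFraction(c(1.8, 2.5, 3.4))
#' @export
setGeneric("tumorFraction", function(object) standardGeneric("tumorFraction"))
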