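#' Mutation dosage from allele counts
#'
#' The mutation dosage is the mutant read count divided by the total read
#' count at the hotspot codon (for DNA assays this is the variant allele
#' frequency). Undefined (NA) when no reads cover the codon.
#'
#' @param x an [AlleleCounts] object.
#' @return a fraction in [0, 1], or \code{NA_real_} when total is 0.
#' @examples
#' computeDosage(AlleleCounts(mutant = 39, wildtype = 161))
#' @export
setGeneric("computeDosage", function(x) standardGeneric("computeDosage"))

#' @rdname kmFit
#' @param curve a [KMCurve].
#' @export
setGeneric("kmMedian", function(curve) standardGeneric("kmMedian"))

#' @rdname kmFit
#' @param t time (months) at which to evaluate S(t).
#' @export
setGeneric("kmRateAt", function(curve, t) standardGeneric("kmRateAt"))

#' @rdname scanCutpoints
#' @param scan a [CutpointScan].
#' @export
setGeneric("selectGlobal", function(scan) standardGeneric("selectGlobal"))

#' @rdname scanCutpoints
#' @param k maximum number of local maxima to return.
#' @export
setGeneric("selectLocalMaxima",
  function(scan, k = 2L) standardGeneric("selectLocalMaxima"))

#' @rdname AlleleCounts-class
#' @param x an [AlleleCounts].
#' @export
setGeneric("mutantReads", function(x) standardGeneric("mutantReads"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("wildtypeReads", function(x) standardGeneric("wildtypeReads"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("otherReads", function(x) standardGeneric("otherReads"))

#' @rdname AlleleCounts-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
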