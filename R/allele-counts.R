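#' Construct AlleleCounts
#'
#' @param mutant,wildtype,other non-negative read counts.
#' @param modality sequencing modality: \code{"RNA"}, \code{"WES"} or
#'   \code{"TS"}.
#' @param codon hotspot codon label.
#' @return an [AlleleCounts-class] object.
#' @examples
#' ac <- AlleleCounts(mutant = 3, wildtype = 7)
#' totalReads(ac)
#' computeDosage(ac)
#' @name AlleleCounts-class
#' @aliases AlleleCounts
#' @export
AlleleCounts <- function(mutant = 0L, wildtype = 0L, other = 0L,
                         modality = "TS", codon = "G12") {
  new("AlleleCounts", mutant = as.integer(mutant),
      wildtype = as.integer(wildtype), other = as.integer(other),
      modality = modality, codon = codon)
}

#' @rdname AlleleCounts-class
#' @export
setMethod("mutantReads", "AlleleCounts", function(x) x@mutant)

#' @rdname AlleleCounts-class
#' @export
setMethod("wildtypeReads", "AlleleCounts", function(x) x@wildtype)

#' @rdname AlleleCounts-class
#' @export
setMethod("otherReads", "AlleleCounts", function(x) x@other)

#' @rdname AlleleCounts-class
#' @export
setMethod("totalReads", "AlleleCounts",
          function(x) x@mutant + x@wildtype + x@other)

setMethod("show", "AlleleCounts", function(object) {
  cat(sprintf("AlleleCounts [%s/%s] mutant=%d wildtype=%d other=%d (total %d)\n",
              object@modality, object@codon, object@mutant, object@wildtype,
              object@other, totalReads(object)))
})

#' @rdname computeDosage
#' @export
setMethod("computeDosage", "AlleleCounts", function(x) {
  tot <- totalReads(x)
  if (tot == 0L) return(NA_real_)
  x@mutant / tot
})
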