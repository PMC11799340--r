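#' Construct a TargetLocus
#'
#' @param chrom chromosome name.
#' @param positions three consecutive ascending 1-based genomic coordinates
#'   of the codon.
#' @param refCodon the three reference bases in genomic (plus-strand)
#'   orientation.
#' @param geneStrand strand the gene is transcribed from.
#' @param build genome-build tag.
#' @return a [TargetLocus-class] object.
#' @export
TargetLocus <- function(chrom, positions, refCodon, geneStrand = "-",
                        build = "hg19") {
  new("TargetLocus", chrom = as.character(chrom),
      positions = as.integer(positions),
      refCodon = toupper(refCodon),
      geneStrand = geneStrand, build = build)
}

# KRAS is transcribed from the minus strand; plus-strand reference codons
# are the reverse complements of the coding codons (G12 = GGT -> ACC,
# Q61 = CAA -> TTG).
.KRAS_PRESETS <- list(
  G12 = list(
    hg19 = list(chrom = "chr12", positions = 25398283:25398285,
                refCodon = "ACC"),
    hg38 = list(chrom = "chr12", positions = 25245349:25245351,
                refCodon = "ACC")
  ),
  Q61 = list(
    hg19 = list(chrom = "chr12", positions = 25380275:25380277,
                refCodon = "TTG"),
    hg38 = list(chrom = "chr12", positions = 25227341:25227343,
                refCodon = "TTG")
  )
)

#' KRAS hotspot codon presets
#'
#' Shipped loci for the KRAS G12 and Q61 hotspot codons in hg19 and hg38
#' coordinates. The G12 codon in hg19 is chr12:25,398,283-25,398,285.
#'
#' @param codon \code{"G12"} or \code{"Q61"}.
#' @param build \code{"hg19"} or \code{"hg38"}.
#' @return a [TargetLocus-class].
#' @examples
#' krasLocus("G12")
#' krasLocus("G12", build = "hg38")
#' @export
krasLocus <- function(codon = c("G12", "Q61"), build = c("hg19", "hg38")) {
  codon <- match.arg(codon)
  build <- match.arg(build)
  p <- .KRAS_PRESETS[[codon]][[build]]
  TargetLocus(p$chrom, p$positions, p$refCodon, geneStrand = "-",
              build = build)
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
lociAsGRanges <- function(locus) {
  GenomicRanges::GRanges(locus@chrom,
    IRanges::IRanges(locus@positions[1], locus@positions[3]),
    strand = "*")
}

setMethod("show", "TargetLocus", function(object) {
  cat(sprintf("TargetLocus (%s) %s:%d-%d [%s] ref codon %s (gene strand %s)\n",
              object@build, object@chrom, object@positions[1],
              object@positions[3], "1-based", object@refCodon,
              object@geneStrand))
})

# coding-orientation amino acid of a genomic-orientation codon
#' @importFrom Biostrings DNAString reverseComplement GENETIC_CODE
.codonAminoAcid <- function(genomicCodon, geneStrand) {
  coding <- if (geneStrand == "-") {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomicCodon)))
  } else genomicCodon
  unname(Biostrings::GENETIC_CODE[coding])
}

# classify a genomic-orientation codon string observed in a read against
# the locus reference: "wildtype", "mutant" (non-synonymous substitution)
# or "other" (anything unclassifiable, including synonymous changes)
classifyCodon <- function(codon, locus) {
  if (is.na(codon) || nchar(codon) != 3L || grepl("[^ACGT]", codon))
    return("other")
  if (codon == locus@refCodon) return("wildtype")
  refAA <- .codonAminoAcid(locus@refCodon, locus@geneStrand)
  aa <- .codonAminoAcid(codon, locus@geneStrand)
  if (!is.na(aa) && aa != refAA) "mutant" else "other"
}
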