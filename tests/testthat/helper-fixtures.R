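# Fixture builders: alignment and VCF files are constructed in code at
# test time around the hg19 G12 locus (chr12:25,398,283-285, plus-strand
# reference codon ACC).

G12_HG19 <- krasLocus("G12", "hg19")

# one plus-strand SAM read; default qualities Q40
samRead <- function(name, pos, seq, mapq = 60L, cigar = NULL, qual = NULL) {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(name, 0L, "chr12", pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

# read whose codon bases (at 25,398,283-285) are `codon`, spanning
# 10 bases of flank on each side
codonRead <- function(name, codon, mapq = 60L, qual = NULL, offset = 10L) {
  seq <- paste0(strrep("G", offset), codon, strrep("T", offset))
  samRead(name, G12_HG19@positions[1] - offset, seq, mapq = mapq,
          qual = qual)
}

makeBam <- function(lines) {
  sam <- tempfile(fileext = ".sam")
  pos <- as.integer(vapply(strsplit(lines, "\t"), `[`, character(1), 4L))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr12\tLN:133851895",
               lines[order(pos)]), sam)
  Rsamtools::asBam(sam, overwrite = TRUE, indexDestination = TRUE)
}

makeVcf <- function(bodyLines, sampleName = "TUMOR") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr12,length=133851895>",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=artifact,Description=\"failed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"),
    bodyLines), path)
  path
}

# shared large cohort for the distribution-level properties; generated
# once per test run
sharedCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateCohort(simulationConfig(n_patients = 2000L,
                                                seed = 20260923L))
    }
    cache
  }
})

sharedProfiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildDosageProfiles(sharedCohort()$counts)
    cache
  }
})
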